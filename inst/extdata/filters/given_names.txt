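# Illustrative given names for the person-page filter
James
John
Maria
Anna
Hans
Iwan
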