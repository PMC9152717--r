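# English abbreviations that end in a period but do not end a sentence
Dr.
Mr.
Mrs.
Ms.
Prof.
St.
vs.
ca.
e.g.
i.e.
etc.
approx.
Fig.
No.
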