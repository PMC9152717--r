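# German abbreviations
Dr.
Prof.
z.B.
z. B.
bzw.
usw.
ca.
u.a.
d.h.
Nr.
Abb.
ggf.
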