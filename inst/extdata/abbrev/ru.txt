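# Russian abbreviations
т.е.
т.д.
т.п.
др.
г.
гг.
см.
напр.
ок.
проф.
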