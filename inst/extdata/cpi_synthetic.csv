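year,cpi
2005,95.25
2009,100.00
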