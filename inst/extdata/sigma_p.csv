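substituent,sigma_p
H,0.00
4-Cl,0.23
4-Br,0.23
4-NMe2,-0.83
4-CN,0.66
4-CF3,0.54
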