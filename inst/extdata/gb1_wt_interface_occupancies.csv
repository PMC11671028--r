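focal_resno,focal_moiety,partner_resno,partner_moiety,occupancy
27,side-chain,253,backbone,0.39
27,side-chain,254,side-chain,0.74
27,side-chain,254,side-chain,0.43
28,side-chain,380,side-chain,0.59
28,side-chain,382,side-chain,0.54
35,side-chain,434,side-chain,0.23
40,side-chain,433,side-chain,0.38
40,side-chain,434,backbone,0.37
43,side-chain,434,side-chain,0.44
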