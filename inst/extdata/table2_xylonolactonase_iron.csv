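L_free_mol_per_L,B_PL
1.70e-8,0.0958
1.34e-8,0.210
1.90e-7,0.276
3.81e-7,0.550
1.22e-6,0.696
3.12e-6,0.785
6.99e-6,0.905
1.50e-5,0.934
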