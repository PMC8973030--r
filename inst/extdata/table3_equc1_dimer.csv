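c_P_mol_per_L,P_free_mol_per_L
6.2e-8,9.74e-9
4.36e-7,4.71e-8
7.47e-7,8.21e-8
1.81e-6,1.19e-7
2.55e-6,1.29e-7
3.68e-6,1.74e-7
4.73e-6,1.84e-7
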