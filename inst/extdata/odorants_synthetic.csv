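name,molar_mass,molar_volume,D_a,D_m,beta
methyl benzoate,136.15,151.0,,,1e-5
isoamyl acetate,130.19,148.9,,,1e-3
cyclohexane,84.16,118.2,,,0.18
ethanol,46.07,59.2,,,2.4e-4
acetone,58.08,74.0,,,1.6e-3
2-heptanone,114.19,162.8,,,6e-3
carvone,150.22,192.2,,,1e-4
limonene,136.23,192.2,,,5e-2
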