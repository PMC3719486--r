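species	unstable	stable	singleton
Arabidopsis_thaliana	203	4	4
Vitis_vinifera	2	3	1
Populus_trichocarpa	9	30	8
Oryza_sativa	2	36	1
Sorghum_bicolor	0	34	3
Selaginella_moellendorffii	0	1	2
Physcomitrella_patens	0	7	0
Coccomyxa_sp	0	0	1
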