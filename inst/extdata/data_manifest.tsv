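file	md5	citation
scale_aggrescan_a3v.tsv	a7480cce27c66770c4f67cbe0322a81b	Conchillo-Sole et al. 2007 BMC Bioinformatics 8:65
scale_beta_propensity.tsv	fbaa8bd85debf85f7ebdb204f248758d	Chou & Fasman 1978 Adv Enzymol 47:45
scale_packing_density_synthetic.tsv	c6a3e3314ea6a5440e1ee7d594890952	synthetic stand-in after Galzitskaya et al. 2006 PLoS Comput Biol 2:e177
pattern_amyloidogenic_hexapeptide.tsv	a58d97f7cf5c8e19685d0fab24ec3bd8	Lopez de la Paz & Serrano 2004 PNAS 101:87
pssm_waltz_ph7_synthetic.tsv	60039fefa941f9b6537f1d5442542550	synthetic stand-in after Maurer-Stroh et al. 2010 Nat Methods 7:237
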