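# Method registry: every threshold, window rule and minimum length for the
# eleven component methods, in canonical order. Boundary semantics follow the
# published wording literally: "above" / "below" are strict, the sliding-
# average propensity minimum (1.2), the PSSM cut-off (79.0; strict setting
# 92.0) and the reliability index (7) are inclusive. params is JSON.
method	kind	label	min_length	data_file	params
aggrescan	native	Aggrescan	1	scale_aggrescan_a3v.tsv	{"threshold":-0.02,"window_rule":[[75,5],[175,7],[300,9],[1000000,11]]}
amylmut	adapter	AmyloidMutants	20	-	{"rule":[{"column":"hit","op":">=","cutoff":1}]}
pattern	native	Amyloidogenic Pattern	6	pattern_amyloidogenic_hexapeptide.tsv	{}
apd	native	Average Packing Density	5	scale_packing_density_synthetic.tsv	{"threshold":21.4,"window":5}
bsc	native	Beta-strand contiguity	1	scale_beta_propensity.tsv	{"mbp_min":1.2,"y_threshold":20,"window_min":4,"window_max":20}
hce	adapter	Hexapeptide Conformational Energy	1	-	{"rule":[{"column":"energy","op":"<","cutoff":-27.0}]}
netcssp	adapter	NetCSSP	7	-	{"derive":{"hbp":["pbeta","phelix"]},"rule":[{"column":"hbp","op":">","cutoff":1},{"column":"pbeta","op":">","cutoff":6}]}
pafig	adapter	Pafig	6	-	{"rule":[{"column":"ri","op":">=","cutoff":7}]}
secstr	adapter	SecStr	1	-	{"rule":[{"column":"switch","op":">=","cutoff":1}]}
tango	adapter	Tango	1	-	{"rule":[{"column":"beta_agg","op":">","cutoff":5.0}]}
waltz	native	Waltz	6	pssm_waltz_ph7_synthetic.tsv	{"threshold":79.0,"threshold_strict":92.0,"window":6}
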