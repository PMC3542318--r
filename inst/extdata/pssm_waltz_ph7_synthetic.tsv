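# SYNTHETIC STAND-IN hexapeptide PSSM (pH-7 style profile). Built by
# data-raw/build_waltz_pssm.R as a pseudocount-smoothed log-odds profile
# over 14 experimentally established amyloid-forming hexapeptides,
# affine-scaled so the achievable window-score range is [0, 100].
# It is NOT the matrix of Maurer-Stroh et al. (2010) Nat Methods 7:237,
# which is not redistributable here; see the package vignette.
position	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
1	9.985	0.000	0.000	0.000	9.985	14.628	0.000	0.000	9.985	9.985	9.985	14.628	0.000	0.000	0.000	17.686	0.000	14.628	0.000	0.000
2	0.000	0.000	0.000	9.985	9.985	14.628	0.000	9.985	0.000	9.985	0.000	17.686	0.000	9.985	0.000	9.985	9.985	9.985	0.000	9.985
3	14.628	0.000	0.000	0.000	0.000	14.628	0.000	14.628	0.000	0.000	0.000	9.985	0.000	17.686	0.000	0.000	9.985	17.686	0.000	0.000
4	9.985	0.000	0.000	0.000	9.985	14.628	0.000	14.628	0.000	14.628	0.000	14.628	0.000	14.628	0.000	0.000	0.000	14.628	0.000	0.000
5	0.000	0.000	0.000	9.985	9.985	0.000	0.000	17.686	0.000	14.628	0.000	14.628	0.000	9.985	0.000	0.000	0.000	14.628	0.000	14.628
6	14.628	0.000	0.000	9.985	9.985	9.985	0.000	0.000	9.985	14.628	9.985	14.628	0.000	0.000	0.000	9.985	0.000	9.985	0.000	9.985
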