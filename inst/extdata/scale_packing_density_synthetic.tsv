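# SYNTHETIC STAND-IN for the expected packing density scale (mean number of
# residue contacts within 8 A) of Galzitskaya et al. (2006) PLoS Comput Biol
# 2:e177. The original numeric table could not be transcribed in this build
# environment; these values reproduce the published ordering (branched
# hydrophobics/aromatics above the 21.4 hit cut-off, polar/charged/P/G
# below). See the package vignette, section "Packaged data provenance".
residue	value
A	20.0
C	23.3
D	17.7
E	17.6
F	23.2
G	18.5
H	20.5
I	23.0
K	16.9
L	22.4
M	22.5
N	18.2
P	17.4
Q	18.5
R	18.3
S	19.4
T	20.1
V	23.0
W	22.6
Y	22.3
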