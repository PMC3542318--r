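# Six-position amyloidogenic sequence pattern from saturation scanning
# mutagenesis of the de novo designed amyloid peptide STVIIE,
# Lopez de la Paz & Serrano (2004) PNAS 101:87-92.
# mode "allowed": window residue must be in the set;
# mode "forbidden": window residue must not be in the set.
position	mode	residues
1	forbidden	P
2	forbidden	PKRHW
3	allowed	VLSCWFNQE
4	allowed	ILTYWFNE
5	allowed	FIY
6	forbidden	PKRH
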