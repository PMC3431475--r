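# Protease specificity tables for the simultaneous gastrointestinal digest,
# transcribed from the ExPASy PeptideCutter models (Keil, Specificity of
# Proteolysis, Springer 1992): trypsin with its exception sub-rules, pepsin
# at pH 1.3, chymotrypsin (high specificity).
# Format: one row per rule line or exception pattern. kind=require gives the
# residue-class context P4..P2' under which the enzyme cleaves the P1|P1'
# bond; kind=except rows attached to the same line block that cleavage when
# their own context holds. Class syntax: residue letters (e.g. "FL"),
# "^XYZ" = any standard residue except those listed, "." = any standard
# residue (position must exist), "-" = unconstrained.
enzyme	line	kind	P4	P3	P2	P1	P1p	P2p
trypsin	t1	require	-	-	-	K	^P	-
trypsin	t1	except	-	-	CD	K	D	-
trypsin	t1	except	-	-	C	K	HY	-
trypsin	t2	require	-	-	-	R	^P	-
trypsin	t2	except	-	-	C	R	K	-
trypsin	t2	except	-	-	R	R	HR	-
trypsin	t3	require	-	-	W	K	P	-
trypsin	t4	require	-	-	M	R	P	-
pepsin_ph1.3	p1	require	-	^HKR	^P	^R	FL	^P
pepsin_ph1.3	p2	require	-	^HKR	^P	FL	.	^P
chymotrypsin_high	c1	require	-	-	-	FY	^P	-
chymotrypsin_high	c2	require	-	-	-	W	^MP	-
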