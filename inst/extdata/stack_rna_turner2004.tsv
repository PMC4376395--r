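# RNA nearest-neighbor stacking free energies, 37 C, kcal/mol (Turner 2004 set).
# Entry [p1, p2] is the stack between adjacent pairs (i,j) and (i+1,j-1), where
# p1 = pair type of (seq[i], seq[j]) and p2 = pair type of (seq[j-1], seq[i+1]).
pair	CG	GC	GU	UG	AU	UA
CG	-2.40	-3.30	-2.10	-1.40	-2.10	-2.10
GC	-3.30	-3.40	-2.50	-1.50	-2.20	-2.40
GU	-2.10	-2.50	1.30	-0.50	-1.40	-1.30
UG	-1.40	-1.50	-0.50	0.30	-0.60	-1.00
AU	-2.10	-2.20	-1.40	-0.60	-1.10	-0.90
UA	-2.10	-2.40	-1.30	-1.00	-0.90	-1.30
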