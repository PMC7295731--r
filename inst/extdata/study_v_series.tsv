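# Published geNorm pairwise-variation values V(n, n+1). The study prints
# only the decision-relevant entries. The N10 n=2 entry is CENSORED: the
# study states every V exceeded 0.15 for that condition and chose three
# genes at the relaxed 0.2 cutoff, so 0.200 here encodes "not below 0.2"
# (the decision rule uses strict <); it is not a measured value.
condition	n	v	censored
N10	2	0.200	TRUE
N10	3	0.195	FALSE
S24	2	0.185	FALSE
mixed	2	0.088	FALSE
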