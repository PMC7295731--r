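# Published per-gene Ct extremes and means over the study's 12 samples
# (cycles); range = max - min.
gene	min	max	mean
18S	10.22	14.18	12.89
actin	19.40	22.55	21.12
GAPDH	23.80	26.24	24.85
UBC	24.46	26.60	25.53
a-tubulin	23.94	27.50	25.68
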