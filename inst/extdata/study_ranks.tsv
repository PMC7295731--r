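# Per-condition stability ranks of five candidate reference genes from a
# published RT-qPCR screen in the rice white-tip nematode: conditions are
# four life stages of population N10, four life stages of population S24,
# and mixed-stage nematodes of four populations. Ties (geNorm's final pair)
# carry the competition-rank convention (1,1,3,...).
method	condition	gene	rank
delta_ct	N10	UBC	1
delta_ct	N10	actin	2
delta_ct	N10	18S	3
delta_ct	N10	a-tubulin	4
delta_ct	N10	GAPDH	5
delta_ct	S24	18S	1
delta_ct	S24	UBC	2
delta_ct	S24	GAPDH	3
delta_ct	S24	actin	4
delta_ct	S24	a-tubulin	5
delta_ct	mixed	UBC	1
delta_ct	mixed	GAPDH	2
delta_ct	mixed	a-tubulin	3
delta_ct	mixed	actin	4
delta_ct	mixed	18S	5
genorm	N10	actin	1
genorm	N10	a-tubulin	1
genorm	N10	18S	3
genorm	N10	UBC	4
genorm	N10	GAPDH	5
genorm	S24	UBC	1
genorm	S24	GAPDH	1
genorm	S24	18S	3
genorm	S24	actin	4
genorm	S24	a-tubulin	5
genorm	mixed	UBC	1
genorm	mixed	GAPDH	1
genorm	mixed	a-tubulin	3
genorm	mixed	actin	4
genorm	mixed	18S	5
normfinder	N10	UBC	1
normfinder	N10	18S	2
normfinder	N10	actin	3
normfinder	N10	a-tubulin	4
normfinder	N10	GAPDH	5
normfinder	S24	UBC	1
normfinder	S24	18S	2
normfinder	S24	GAPDH	3
normfinder	S24	actin	4
normfinder	S24	a-tubulin	5
normfinder	mixed	UBC	1
normfinder	mixed	GAPDH	2
normfinder	mixed	a-tubulin	3
normfinder	mixed	actin	4
normfinder	mixed	18S	5
reffinder	N10	UBC	1
reffinder	N10	actin	2
reffinder	N10	18S	3
reffinder	N10	a-tubulin	4
reffinder	N10	GAPDH	5
reffinder	S24	UBC	1
reffinder	S24	18S	2
reffinder	S24	GAPDH	3
reffinder	S24	actin	4
reffinder	S24	a-tubulin	5
reffinder	mixed	UBC	1
reffinder	mixed	GAPDH	2
reffinder	mixed	a-tubulin	3
reffinder	mixed	actin	4
reffinder	mixed	18S	5
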