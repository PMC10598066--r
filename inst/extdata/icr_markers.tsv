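# SSLP markers delimiting the Cati1/Cati2 cataract loci of the ICR rat.
# mRatBN7.2 positions are the published coordinates. The two Rnor_6.0 rows
# are SYNTHETIC placeholders: only their inter-marker distance (20,135,471
# bases between D15Rat52 and D15Rat20) is real, derived from the published
# mRatBN7.2 interval; the absolute Rnor_6.0 positions are round-number
# stand-ins for demonstration of the colinear-offset estimator.
name	assembly	chrom	pos
D8Rat68	mRatBN7.2	chr8	18984168
D8N136	mRatBN7.2	chr8	84531276
D8Rat80	mRatBN7.2	chr8	47353202
D8Rat43	mRatBN7.2	chr8	48630131
Thy1	mRatBN7.2	chr8	44393886
Cyp1a1	mRatBN7.2	chr8	58098974
D15Rat20	mRatBN7.2	chr15	52813021
D15Rat20	Rnor_6.0	chr15	53035471
D15Rat52	Rnor_6.0	chr15	32900000
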