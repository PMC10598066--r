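gene	chrom	pos	ref	alt	so_terms	genotype	assembly
Apoc3	chr8	46532966	C	T	missense_variant	hom_alt	mRatBN7.2
RGD1305464	chr8	57650592	GCAGGGA	G	disruptive_inframe_deletion	hom_alt	mRatBN7.2
Phf11b	chr15	33378050	T	G	stop_lost	hom_alt	mRatBN7.2
Fdft1	chr15	37423413	A	T	missense_variant	hom_alt	mRatBN7.2
Ppk	chr15	40027471	GGTGAGTGAGTGA	G	splice_donor_variant&splice_region_variant&intron_variant	hom_alt	mRatBN7.2
Nkx2-6	chr15	44446376	G	C	missense_variant	hom_alt	mRatBN7.2
Sucla2	chr15	48760331	T	TGCA	conservative_inframe_insertion	hom_alt	mRatBN7.2
Gja8	chr2	184491323	C	A	missense_variant	hom_alt	mRatBN7.2
Srebf2	chr7	113719718	TTTTTG	T	splice_donor_variant&3_prime_UTR_variant&intron_variant	hom_alt	mRatBN7.2
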