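# SYNTHETIC stand-in for the non-affected strain panel call sets: it carries
# the single published membership fact that the Fdft1 chr15 variant is also
# present in cataract-free strains (it is shared with the SCR model and was
# therefore excluded by the panel rule).
strain	chrom	pos	ref	alt	genotype
F344-stm	chr15	37423413	A	T	hom_alt
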