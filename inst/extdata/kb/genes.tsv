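symbol	input_mode	phenotype_scale	categorical_terms	phenoconversion_eligible
CYP2B6	star_diplotype	poor metabolizer|intermediate metabolizer|normal metabolizer|rapid metabolizer|ultrarapid metabolizer		TRUE
CYP2C19	star_diplotype	poor metabolizer|intermediate metabolizer|normal metabolizer|rapid metabolizer|ultrarapid metabolizer		TRUE
CYP2C9	star_diplotype	poor metabolizer|intermediate metabolizer|normal metabolizer		TRUE
CYP2D6	star_diplotype	poor metabolizer|intermediate metabolizer|normal metabolizer|ultrarapid metabolizer		TRUE
CYP3A5	star_diplotype	poor metabolizer|intermediate metabolizer|normal metabolizer		TRUE
HLA-A	hla_presence		*31:01 positive|*31:01 negative	FALSE
HLA-B	hla_presence		*57:01 positive|*57:01 negative|*58:01 positive|*58:01 negative|*15:02 positive|*15:02 negative	FALSE
NUDT15	star_diplotype		poor metabolizer|intermediate metabolizer|normal metabolizer	FALSE
SLCO1B1	star_diplotype		poor function|decreased function|normal function	FALSE
TPMT	star_diplotype		poor metabolizer|intermediate metabolizer|normal metabolizer	FALSE
VKORC1	variant_genotype		normal sensitivity|increased sensitivity|high sensitivity	FALSE
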