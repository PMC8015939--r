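gene	diplotype	phenotype
CYP2B6	*1/*1	normal metabolizer
CYP2B6	*1/*6	intermediate metabolizer
CYP2B6	*6/*6	poor metabolizer
CYP2B6	*1/*4	rapid metabolizer
CYP2B6	*4/*4	ultrarapid metabolizer
CYP2C19	*1/*1	normal metabolizer
CYP2C19	*1/*2	intermediate metabolizer
CYP2C19	*1/*3	intermediate metabolizer
CYP2C19	*2/*2	poor metabolizer
CYP2C19	*2/*3	poor metabolizer
CYP2C19	*1/*17	rapid metabolizer
CYP2C19	*17/*17	ultrarapid metabolizer
CYP2C9	*1/*1	normal metabolizer
CYP2C9	*1/*2	intermediate metabolizer
CYP2C9	*1/*3	intermediate metabolizer
CYP2C9	*2/*2	intermediate metabolizer
CYP2C9	*2/*3	poor metabolizer
CYP2C9	*3/*3	poor metabolizer
CYP2D6	*1/*1	normal metabolizer
CYP2D6	*1/*2	normal metabolizer
CYP2D6	*2/*2	normal metabolizer
CYP2D6	*1/*4	intermediate metabolizer
CYP2D6	*1/*5	intermediate metabolizer
CYP2D6	*4/*4	poor metabolizer
CYP2D6	*3/*4	poor metabolizer
CYP2D6	*4/*5	poor metabolizer
CYP2D6	*1/*1x2	ultrarapid metabolizer
CYP2D6	*2/*2x2	ultrarapid metabolizer
CYP3A5	*1/*1	normal metabolizer
CYP3A5	*1/*3	intermediate metabolizer
CYP3A5	*3/*3	poor metabolizer
HLA-A	*31:01 positive	*31:01 positive
HLA-A	*31:01 negative	*31:01 negative
HLA-B	*57:01 positive	*57:01 positive
HLA-B	*57:01 negative	*57:01 negative
HLA-B	*58:01 positive	*58:01 positive
HLA-B	*58:01 negative	*58:01 negative
HLA-B	*15:02 positive	*15:02 positive
HLA-B	*15:02 negative	*15:02 negative
NUDT15	*1/*1	normal metabolizer
NUDT15	*1/*3	intermediate metabolizer
NUDT15	*3/*3	poor metabolizer
SLCO1B1	*1/*1	normal function
SLCO1B1	*1/*5	decreased function
SLCO1B1	*1/*15	decreased function
SLCO1B1	*5/*5	poor function
SLCO1B1	*15/*15	poor function
TPMT	*1/*1	normal metabolizer
TPMT	*1/*2	intermediate metabolizer
TPMT	*1/*3A	intermediate metabolizer
TPMT	*2/*3A	poor metabolizer
TPMT	*3A/*3A	poor metabolizer
VKORC1	G/G	normal sensitivity
VKORC1	A/G	increased sensitivity
VKORC1	A/A	high sensitivity
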