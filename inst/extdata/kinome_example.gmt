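kinome	illustrative protein-kinase list (synthetic, not a curated kinome)	CDK2	CDK4	CDK6	PAK1	PAK2	PAK4	GSK3B	STAT1	ITPKB	FN3K	ATM	JAK1
druggable_kinome	illustrative druggable subset (synthetic)	CDK2	CDK4	CDK6	PAK1	PAK4
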