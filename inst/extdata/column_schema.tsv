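table	column	type	description
tpp_table	feature_id	text	opaque feature identifier; phosphosites use PROTEIN_pS123-style suffixes
tpp_table	feature_level	enum	protein or peptide
tpp_table	cell_line	text	cell line name
tpp_table	treatment	enum	vehicle or drug
tpp_table	layout	enum	lysate or intact (drug added to extract vs to living cells)
tpp_table	replicate	integer	biological replicate index (1-based)
tpp_table	T<temp>	real	reporter intensity at <temp> degC; exactly ten channels, ascending; empty cell = absent
expression_table	feature_id	text	protein or phosphopeptide identifier
expression_table	feature_level	enum	protein or phosphopeptide
expression_table	localization_probability	real	phosphosite localization confidence in [0,1]; empty for proteins
expression_table	<cell_line>|<treatment>|R<rep>	real	label-free intensity for one sample; treatment is DMSO, BRAFi, Hsp90i or combo
dose_matrix	dose	real	drug-1 dose (rows); header row carries drug-2 doses; both ascending from 0
dose_matrix	<dose2>	real	viability fraction relative to the vehicle (0,0) well
gmt	term	text	first field per line; second field is a free-text description; remaining fields are member ids
fits	p	real	fitted plateau (fraction soluble at high temperature)
fits	a	real	sigmoid shape parameter (degC units, enters as a/T)
fits	b	real	sigmoid shape parameter (unitless)
fits	tm	real	melting point in degC; empty when undefined
fits	r2	real	coefficient of determination of the sigmoid fit
fits	min_slope	real	steepest slope of the fitted curve in 1/degC (negative for melters)
fits	converged	logical	whether the least-squares fit converged
fits	status	enum	ok, flat, nonconverged or unusable
shifts	dtm_<k>	real	melting-point difference (side A - side B) for replicate pair k, degC
shifts	p_<k>	real	robust-z two-sided p-value for replicate pair k
shifts	padj_<k>	real	Benjamini-Hochberg adjusted p for replicate pair k
shifts	stability_dtm	real	reference-side replicate |Tm| difference, degC
shifts	same_sign	logical	all replicate-pair shifts share a sign
shifts	qc_pass	logical	both curves pass quality gates in every pair
shifts	significant	logical	full replicate-concordant hit verdict
shifts	reasons	text	semicolon-separated reason codes for non-hits
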