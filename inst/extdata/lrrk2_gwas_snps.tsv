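id	chrom	pos	association_population
rs1994090	12	38714828	Japanese
rs11564162	12	38729159	Caucasian
rs7304279	12	38752209	Japanese
rs4768212	12	38760414	Japanese
rs2708453	12	38764919	Japanese
rs2896905	12	38779683	Caucasian
rs2046932	12	38866707	Japanese
rs1491923	12	38877384	Caucasian
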