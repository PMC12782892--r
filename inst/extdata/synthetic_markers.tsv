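marker_id	chrom	pos	alleles	class
SNP388	Chr16	9128903	G,A	functional
SNP657	Chr03	35391111	T,A	functional
SNP167	Chr16	38704799	C,G	functional
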