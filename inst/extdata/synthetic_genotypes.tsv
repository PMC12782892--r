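individual_id	SNP388	SNP657	SNP167
HYB_0001	A/G	A/A	C/C
HYB_0002	A/A	T/T	C/C
HYB_0003	A/G	.	C/G
HYB_0004	G/G	A/T	C/G
HYB_0005	A/A	A/A	C/C
HYB_0006	.	T/T	G/G
HYB_0007	G/G	A/T	.
HYB_0008	A/G	A/T	C/C
HYB_0009	A/G	A/A	C/G
HYB_0010	.	A/A	C/G
HYB_0011	A/G	T/T	G/G
HYB_0012	A/G	A/A	G/G
HYB_0013	A/A	A/T	C/C
HYB_0014	A/G	T/T	C/C
HYB_0015	A/G	A/T	C/G
HYB_0016	A/A	A/T	G/G
HYB_0017	A/G	A/A	G/G
HYB_0018	G/G	A/T	G/G
HYB_0019	A/G	A/A	C/C
HYB_0020	G/G	A/T	C/G
HYB_0021	A/G	A/T	C/G
HYB_0022	A/G	T/T	C/G
HYB_0023	A/G	T/T	C/C
HYB_0024	A/G	A/T	C/C
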