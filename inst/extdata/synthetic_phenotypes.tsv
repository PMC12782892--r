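individual_id	trait	value	unit
HYB_0001	FFR	5.096	months
HYB_0002	FFR	7.462	months
HYB_0003	FFR	5.215	months
HYB_0004	FFR	7.004	months
HYB_0005	FFR	3.002	months
HYB_0006	FFR	6.462	months
HYB_0007	FFR	7.488	months
HYB_0008	FFR	6.817	months
HYB_0009	FFR	5.895	months
HYB_0010	FFR	4.642	months
HYB_0011	FFR	6.058	months
HYB_0012	FFR	4.045	months
HYB_0013	FFR	5.016	months
HYB_0014	FFR	7.89	months
HYB_0015	FFR	6.898	months
HYB_0016	FFR	3.877	months
HYB_0017	FFR	6.031	months
HYB_0018	FFR	7.112	months
HYB_0019	FFR	6.686	months
HYB_0020	FFR	7.505	months
HYB_0021	FFR	7.199	months
HYB_0022	FFR	9.186	months
HYB_0023	FFR	8.69	months
HYB_0024	FFR	7.078	months
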