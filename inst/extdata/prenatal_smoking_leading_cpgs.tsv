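cpg_id	chromosome	gene	beta	se	pval	dose_beta	dose_se	dose_pval
cg15325070	1	NA	0.014	0.003	9.23E-08	0.168	0.034	6.81E-07
cg25189904	1	GNG12	-0.020	0.003	1.28E-10	-0.146	0.032	5.85E-06
cg14179389	1	GFI1	-0.028	0.003	5.00E-20	-0.214	0.031	4.92E-12
cg04749740	2	NA	0.015	0.003	9.21E-08	0.061	0.034	6.98E-02
cg06635952	2	ANXA4	0.011	0.002	5.54E-08	0.073	0.029	1.12E-02
cg11025974	2	CACNB4	0.016	0.002	9.06E-11	0.169	0.033	2.19E-07
cg14157435	2	NRP2	-0.046	0.006	1.15E-13	-0.201	0.033	9.33E-10
cg05783384	2	NA	0.021	0.004	2.59E-08	0.097	0.033	3.26E-03
cg05204104	2	ARL4C	0.017	0.003	4.81E-12	0.036	0.033	2.73E-01
cg00174179	3	RHOA	-0.006	0.001	7.01E-09	-0.104	0.029	3.89E-04
cg16449012	4	FAM184B	0.014	0.002	3.10E-08	0.119	0.030	7.81E-05
cg05575921	5	AHRR	-0.019	0.002	3.53E-18	-0.134	0.027	5.91E-07
cg21253335	5	NA	0.017	0.003	1.25E-08	0.108	0.033	1.04E-03
cg01952185	5	NA	0.019	0.003	3.31E-12	0.128	0.030	1.67E-05
cg05634495	6	NA	0.016	0.003	3.14E-08	0.088	0.033	6.86E-03
cg00794911	6	NA	-0.012	0.002	5.20E-10	-0.115	0.034	6.42E-04
cg25879142	7	NA	0.018	0.003	1.79E-08	0.121	0.031	1.23E-04
cg20117519	7	NA	0.022	0.004	2.39E-08	0.112	0.033	6.72E-04
cg19089201	7	MYO1G	0.035	0.003	1.18E-31	0.225	0.032	2.24E-12
cg04598670	7	NA	-0.019	0.003	8.33E-08	-0.178	0.034	1.54E-07
cg25949550	7	CNTNAP2	-0.007	0.001	5.41E-27	-0.157	0.022	1.65E-12
cg11207515	7	CNTNAP2	-0.023	0.003	1.03E-13	-0.145	0.032	7.02E-06
cg15578140	7	MIR548F3	0.011	0.002	7.54E-09	0.152	0.031	1.12E-06
cg17199018	8	ZNF395	-0.017	0.003	3.85E-09	-0.121	0.033	2.63E-04
cg14563637	9	NA	0.016	0.003	1.19E-09	0.092	0.031	3.26E-03
cg14540913	9	PRRX2	0.013	0.002	7.57E-09	0.148	0.032	2.62E-06
cg13822849	9	OLFM1	0.007	0.001	2.87E-08	0.126	0.030	3.24E-05
cg11813497	10	FRMD4A	0.026	0.003	9.27E-19	0.117	0.032	2.81E-04
cg05697249	11	C11orf52	0.015	0.002	1.30E-11	0.136	0.035	8.25E-05
cg18493761	11	NA	0.037	0.004	7.30E-21	0.154	0.034	4.82E-06
cg05549655	15	CYP1A1	0.010	0.001	1.04E-28	0.230	0.028	1.92E-16
cg13834112	15	NA	0.013	0.002	3.55E-08	0.120	0.031	1.24E-04
cg00253658	16	NA	0.037	0.004	3.44E-19	0.166	0.033	4.83E-07
cg04358214	16	C16orf70	0.022	0.004	9.56E-08	0.090	0.031	3.94E-03
cg12984635	19	ETHE1	0.015	0.002	2.17E-09	0.116	0.031	1.49E-04
cg06758350	21	RUNX1	0.030	0.005	1.68E-10	0.140	0.034	3.92E-05
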