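gene	luma	lumb	her2	basal	normal	group
ACTR3B	-0.76	-0.454	-0.034	1.38	0.232	basal
ANLN	-0.718	0.748	0.616	1.048	-1.164	proliferation
BAG1	0.793	0.463	-0.611	-1.197	0.378	er
BCL2	1.211	0.65	-0.75	-1.071	0.216	er
BIRC5	-0.926	0.712	0.538	1.014	-0.843	proliferation
BLVRA	1.069	0.646	-0.366	-0.768	0.034	er
CCNB1	-0.795	0.562	0.617	1.006	-0.928	proliferation
CCNE1	-0.688	-0.429	-0.166	1.162	0.433	basal
CDC20	-0.721	1.053	0.166	0.905	-1.056	proliferation
CDC6	-1.059	0.885	0.614	0.785	-0.833	proliferation
CDH3	-0.528	-0.406	-0.078	1.082	0.13	basal
CENPF	-0.842	1.2	0.675	0.946	-0.867	proliferation
CEP55	-0.746	0.853	0.742	1.13	-1.062	proliferation
CXXC5	0.618	0.426	-0.588	-1.257	0.085	er
EGFR	-0.929	-0.384	-0.075	0.993	0.338	basal
ERBB2	-0.403	0.153	1.487	-0.13	-0.31	her2
ESR1	0.771	0.599	-0.524	-1.116	0.422	er
EXO1	-0.889	0.746	0.351	0.807	-1.008	proliferation
FGFR4	-0.184	0.135	1.552	-0.613	-0.257	her2
FOXA1	1.013	0.553	-0.325	-1.278	0.244	er
FOXC1	-0.866	-0.715	-0.378	0.987	0.053	basal
GPR160	1.163	0.493	-0.422	-0.927	0.022	er
GRB7	-0.292	-0.022	1.609	-0.29	-0.295	her2
KIF2C	-0.654	0.885	0.378	1.016	-1.306	proliferation
KRT14	-0.673	-0.735	-0.32	0.867	0.351	basal
KRT17	-0.702	-0.684	0.065	1.199	0.311	basal
KRT5	-0.874	-0.74	-0.255	1.13	0.289	basal
MAPT	1.001	0.515	-0.59	-0.919	0.013	er
MDM2	0.717	0.528	-0.617	-0.744	0.173	er
MELK	-1.017	0.804	0.526	0.86	-1.007	proliferation
MIA	-0.702	-0.675	-0.314	1.35	0.342	basal
MKI67	-0.756	0.83	0.602	1.016	-0.812	proliferation
MLPH	1.053	0.716	-0.433	-0.988	0.2	er
MMP11	0.122	0.318	0.142	0.496	0.065	other
MYBL2	-0.717	0.672	0.651	0.904	-0.807	proliferation
MYC	-0.834	-0.713	-0.058	1.384	0.368	basal
NAT1	0.827	0.326	-0.469	-1.103	0.162	er
NDC80	-0.875	0.63	0.305	0.75	-0.935	proliferation
NUF2	-0.771	0.89	0.252	1.082	-0.713	proliferation
ORC6	-0.868	0.636	0.749	1.011	-1.012	proliferation
PGR	1.006	0.429	-0.651	-0.986	0.134	er
PHGDH	-0.556	-0.524	-0.23	1.17	0.071	basal
PTTG1	-0.854	0.803	0.775	0.883	-0.78	proliferation
RRM2	-0.824	0.862	0.47	0.96	-1.052	proliferation
SFRP1	-0.804	-0.422	-0.136	1.271	0.215	basal
SLC39A6	1.166	0.416	-0.532	-0.672	-0.086	er
TMEM45B	0.877	0.683	-0.479	-1.119	0.194	er
TYMS	-0.915	1.076	0.391	1.142	-0.973	proliferation
UBE2C	-0.975	0.861	0.4	0.844	-1.181	proliferation
UBE2T	-0.849	0.859	0.579	1.062	-0.73	proliferation
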