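locus,snp_id,maf_replication,maf_discovery,chi_squared,p_value,replaced_from,ld_r2
IQCJ,rs62270407,0.30,0.28,0.28,0.59,,
IQCJ,rs7639707,0.06,0.043,0.58,0.45,,
NXPH1,rs12702829,0.34,0.43,4.0,0.046,,
NXPH1,rs1837523,0.24,0.26,0.25,0.62,,
NXPH1,rs1990554,0.01,0.01,0.03,0.87,,
NXPH1,rs6951762,0.14,0.16,0.23,0.63,rs6966968,0.73
NXPH1,rs10224945,0.11,0.10,0.35,0.55,rs78943417,1.00
NXPH1,rs28473103,0.34,0.36,0.24,0.63,,
NXPH1,rs28673635,0.16,0.15,0.10,0.75,,
NXPH1,rs293180,0.11,0.10,0.003,0.96,,
NXPH1,rs61569932,0.004,0.01,0.80,0.37,,
NXPH1,rs6463808,0.14,0.18,1.19,0.27,,
PHF17,rs114348423,0.008,0.02,1.52,0.22,,
PHF17,rs28437435,0.16,0.35,25.65,4.1e-07,rs1216346,0.91
PHF17,rs75007521,0.02,0.029,0.89,0.34,,
MYB,rs210962,0.20,0.25,1.79,0.18,,
MYB,rs2050017,0.15,0.15,0.02,0.90,rs6933462,1.00
MYB,rs72560788,0.08,0.09,0.09,0.76,,
MYB,rs72974149,0.08,0.09,0.38,0.54,,
NELL1,rs117114492,0.02,0.02,0.05,0.83,,
NELL1,rs78786240,0.08,0.03,8.07,0.005,,
NELL1,rs1850875,0.46,0.42,0.91,0.34,,
NELL1,rs11025436,0.19,0.13,3.07,0.08,rs79624996,0.97
SLIT2,rs143662727,0.05,0.02,3.02,0.08,,
SLIT2,rs16869663,0.07,0.07,0.08,0.77,,
SLIT2,rs1216349,0.31,0.11,34.25,4.9e-09,rs184945470,0.96
SLIT2,rs61790364,0.24,0.18,2.76,0.10,,
SLIT2,rs13137813,0.50,0.45,1.55,0.21,rs10009535,1.00
SLIT2,rs73241936,0.20,0.15,1.98,0.16,,
SLIT2,rs76015249,0.01,0.011,0.03,0.87,,
SLIT2,rs10009109,0.44,0.45,0.02,0.88,,
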