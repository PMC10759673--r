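formula_id,display_name,acc,se,sp,yi,auc,ppv,npv,for
sb,S & B,0.884,0.348,0.977,0.325,0.662,0.719,0.897,0.101
ef,E & F,0.870,0.212,0.983,0.196,0.598,0.685,0.879,0.119
mentzer,Mentzer,0.898,0.464,0.973,0.437,0.718,0.745,0.913,0.084
rbc,RBC,0.871,0.433,0.947,0.380,0.690,0.583,0.907,0.089
shine_lal,S & L,0.783,0.950,0.754,0.705,0.852,0.399,0.989,0.008
rdw,RDW,0.660,0.011,0.772,-0.217,0.391,0.008,0.819,0.145
ricerca,Ricerca,0.374,0.760,0.307,0.067,0.534,0.159,0.881,0.040
green_king,G & K,0.869,0.270,0.972,0.241,0.621,0.621,0.886,0.112
das_gupta,Das Gupta,0.695,0.527,0.724,0.251,0.626,0.247,0.899,0.075
telmissani_mchd,Telmissani-MCHD,0.317,0.939,0.210,0.149,0.575,0.170,0.952,0.010
telmissani_mdhl,Telmissani-MDHL,0.859,0.164,0.979,0.143,0.571,0.571,0.872,0.126
jayabose_rdwi,Jayabose-RDWI,0.876,0.392,0.959,0.350,0.675,0.621,0.902,0.095
huber_herklotz,Huber-Herklotz,0.837,0.013,0.979,-0.008,0.496,0.097,0.852,0.145
sirdah,Sirdah,0.889,0.338,0.984,0.322,0.661,0.787,0.896,0.102
kerman_1,Kerman-I,0.892,0.630,0.937,0.568,0.784,0.634,0.936,0.060
kerman_2,Kerman-II,0.899,0.488,0.969,0.457,0.729,0.731,0.917,0.081
ehsani,Ehsani,0.898,0.475,0.971,0.446,0.723,0.740,0.915,0.083
keikhaei,Keikhaei,0.877,0.311,0.975,0.286,0.643,0.681,0.892,0.106
wongprachum,Wongprachum,0.846,0.286,0.942,0.229,0.614,0.460,0.885,0.109
nishad,Nishad,0.892,0.570,0.947,0.517,0.759,0.650,0.928,0.069
sehgal,Sehgal,0.887,0.497,0.942,0.439,0.720,0.549,0.930,0.067
sargolzaie,Sargolzie,0.832,0.269,0.929,0.198,0.599,0.396,0.881,0.112
pornprasert,Pornprasert,0.758,0.387,0.822,0.209,0.605,0.272,0.886,0.095
sirachainan,Sirachainan,0.631,0.111,0.721,-0.169,0.416,0.064,0.825,0.133
bordbar,Bordbar,0.719,0.832,0.699,0.531,0.766,0.322,0.960,0.028
hameed,Hameed,0.150,0.992,0.006,-0.002,0.499,0.147,0.804,0.001
hisham,Hisham,0.882,0.351,0.973,0.324,0.662,0.694,0.897,0.100
matos,Matos,0.825,0.302,0.915,0.217,0.609,0.380,0.884,0.107
ravanbakhsh_f1,Ravanbakhsh-F1,0.870,0.449,0.942,0.391,0.696,0.572,0.909,0.087
ravanbakhsh_f2,Ravanbakhsh-F2,0.690,0.330,0.752,0.082,0.541,0.186,0.867,0.103
ravanbakhsh_f3,Ravanbakhsh-F3,0.866,0.390,0.948,0.338,0.669,0.565,0.900,0.095
ravanbakhsh_f4,Ravanbakhsh-F4,0.818,0.891,0.805,0.697,0.848,0.441,0.977,0.018
zaghloul_1,Zaghloul-1,0.149,0.992,0.004,-0.003,0.498,0.146,0.763,0.001
zaghloul_2,Zaghloul-2,0.151,0.990,0.006,-0.004,0.498,0.146,0.774,0.002
kandhro_1,Kandhro-1,0.372,0.191,0.403,-0.406,0.297,0.052,0.743,0.122
kandhro_2,Kandhro-2,0.689,0.360,0.745,0.106,0.553,0.196,0.871,0.099
merdin_1,Merdin-1,0.864,0.585,0.912,0.497,0.748,0.533,0.927,0.067
merdin_2,Merdin-2,0.869,0.366,0.956,0.321,0.661,0.587,0.897,0.098
cruise,Cruise,0.363,0.755,0.296,0.051,0.526,0.156,0.876,0.040
janel_11t,Janel (11T),0.887,0.283,0.991,0.274,0.637,0.840,0.889,0.110
index26,Index26,0.893,0.332,0.989,0.321,0.660,0.839,0.896,0.103
scs_btt,SCS_BTT,0.726,0.974,0.684,0.658,0.829,0.346,0.993,0.004
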