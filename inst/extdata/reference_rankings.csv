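formula_id,topsis_dpos,topsis_dneg,topsis_c,topsis_rank,copras_sratio,copras_q,copras_u,copras_rank,seca_score,seca_rank
sb,0.088,0.028,0.243,23,0.044,0.407,59.487,16,0.617,16
ef,0.105,0.013,0.111,34,0.037,0.337,49.306,25,0.553,24
mentzer,0.072,0.043,0.374,15,0.053,0.467,68.253,9,0.672,8
rbc,0.077,0.038,0.330,17,0.050,0.414,60.422,15,0.618,15
shine_lal,0.009,0.109,0.927,1,0.528,0.633,92.463,2,0.801,2
ricerca,0.049,0.076,0.606,6,0.113,0.260,37.934,32,0.394,34
green_king,0.098,0.018,0.156,32,0.040,0.350,51.096,24,0.562,23
das_gupta,0.068,0.046,0.402,12,0.059,0.315,46.065,27,0.498,29
telmissani_mchd,0.034,0.102,0.747,5,0.431,0.362,52.882,23,0.484,31
telmissani_mdhl,0.112,0.009,0.072,35,0.036,0.292,42.673,30,0.510,26
jayabose_rdwi,0.082,0.033,0.285,18,0.047,0.404,59.066,17,0.611,19
sirdah,0.089,0.028,0.236,24,0.044,0.417,60.906,14,0.627,13
kerman_1,0.050,0.065,0.567,8,0.075,0.517,75.570,4,0.713,4
kerman_2,0.069,0.046,0.402,13,0.055,0.475,69.453,7,0.679,6
ehsani,0.071,0.045,0.387,14,0.054,0.471,68.843,8,0.675,7
keikhaei,0.093,0.023,0.201,27,0.042,0.382,55.741,22,0.592,21
wongprachum,0.096,0.018,0.159,31,0.041,0.318,46.478,26,0.528,25
nishad,0.058,0.057,0.495,11,0.065,0.493,72.082,5,0.692,5
sehgal,0.057,0.056,0.495,10,0.067,0.440,64.240,11,0.643,11
sargolzaie,0.099,0.015,0.135,33,0.040,0.293,42.856,29,0.503,28
pornprasert,0.085,0.028,0.249,21,0.047,0.288,42.099,31,0.485,30
bordbar,0.025,0.090,0.781,4,0.159,0.481,70.335,6,0.651,10
hisham,0.087,0.028,0.245,22,0.045,0.403,58.826,18,0.612,18
matos,0.095,0.019,0.168,30,0.042,0.301,44.042,28,0.509,27
ravanbakhsh_f1,0.075,0.040,0.348,16,0.052,0.418,61.014,13,0.621,14
ravanbakhsh_f2,0.095,0.020,0.174,29,0.043,0.218,31.836,35,0.410,33
ravanbakhsh_f3,0.083,0.032,0.280,19,0.047,0.390,56.920,20,0.596,20
ravanbakhsh_f4,0.014,0.101,0.876,3,0.243,0.585,85.497,3,0.761,3
kandhro_2,0.091,0.024,0.207,26,0.045,0.232,33.912,34,0.423,32
merdin_1,0.056,0.058,0.506,9,0.067,0.467,68.200,10,0.663,9
merdin_2,0.086,0.029,0.254,20,0.045,0.384,56.142,21,0.592,22
cruise,0.050,0.075,0.599,7,0.111,0.252,36.877,33,0.386,35
janel_11t,0.096,0.022,0.184,28,0.041,0.402,58.711,19,0.614,17
index26,0.089,0.027,0.233,25,0.043,0.425,62.081,12,0.635,12
scs_btt,0.010,0.112,0.922,2,1.000,0.684,100.000,1,0.845,1
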