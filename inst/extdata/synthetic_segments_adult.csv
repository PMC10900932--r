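site,segment_id,shape,dims,ct_th,coverage,tb_th,tb_sp,bvtv,bvtv_min,bvtv_max,marrow_mass,macro_cv,ct_th_cv,tb_th_cv,tb_sp_cv
head,head_01,deformed_cylinder,1.681;2.576;2.114;1.115;3.624,0.094,1;0;0,0.0148,0.026,0.31,0.186,0.434,146.6,0.16,0.42,0.04,0.04
cervical_spine,cervical_spine_01,elliptic_cylinder,0.896;1.148;1.682,0.041,1;0;0,0.0178,0.0413,0.214,0.128,0.3,12.7,0.16,0.42,0.04,0.04
cervical_spine,cervical_spine_02,elliptic_cylinder,0.871;0.61;1.184,0.021,1;0;0,0.0143,0.0328,0.217,0.13,0.304,12.9,0.16,0.42,0.04,0.04
cervical_spine,cervical_spine_03,box,1.674;1.434;0.833,0.02,1;1;1;1;1;1,0.0139,0.0297,0.24,0.144,0.336,10.6,0.16,0.42,0.04,0.04
thoracic_spine,thoracic_spine_01,elliptic_cylinder,1.194;1.747;2.643,0.026,1;0;0,0.0111,0.0348,0.138,0.083,0.193,29.8,0.16,0.42,0.04,0.04
thoracic_spine,thoracic_spine_02,box,1.761;1.168;1.225,0.044,1;1;1;1;1;1,0.0212,0.0523,0.196,0.118,0.274,29.6,0.16,0.42,0.04,0.04
thoracic_spine,thoracic_spine_03,elliptic_cylinder,2.184;2.287;2.295,0.03,1;0;0,0.022,0.0563,0.186,0.112,0.26,30.9,0.16,0.42,0.04,0.04
thoracic_spine,thoracic_spine_04,elliptic_cylinder,1.759;1.575;1.797,0.047,1;0;0,0.0102,0.0288,0.161,0.097,0.225,24,0.16,0.42,0.04,0.04
thoracic_spine,thoracic_spine_05,box,2.488;2.477;2.01,0.048,1;1;1;1;1;1,0.0097,0.029,0.148,0.089,0.207,20.8,0.16,0.42,0.04,0.04
lumbar_spine,lumbar_spine_01,box,1.799;0.895;1.146,0.032,1;1;1;1;1;1,0.0167,0.0599,0.112,0.067,0.157,18.9,0.16,0.42,0.04,0.04
lumbar_spine,lumbar_spine_02,box,1.779;0.871;1.415,0.03,1;1;1;1;1;1,0.021,0.0702,0.125,0.075,0.175,27.7,0.16,0.42,0.04,0.04
lumbar_spine,lumbar_spine_03,deformed_cylinder,1.9;3.473;2.447;1.398;3.485,0.055,1;0;0,0.0185,0.0631,0.121,0.073,0.169,30.4,0.16,0.42,0.04,0.04
lumbar_spine,lumbar_spine_04,box,4.054;3.604;2.886,0.055,1;1;1;1;1;1,0.0246,0.0684,0.165,0.099,0.231,22.7,0.16,0.42,0.04,0.04
lumbar_spine,lumbar_spine_05,elliptic_cylinder,1.325;2.108;2.189,0.034,1;0;0,0.016,0.0564,0.115,0.069,0.161,24.3,0.16,0.42,0.04,0.04
sternum,sternum_01,elliptic_cylinder,1.244;0.808;1.54,0.035,1;0;0,0.0142,0.0405,0.159,0.095,0.223,12.7,0.16,0.42,0.04,0.04
sternum,sternum_02,box,0.884;0.478;0.449,0.039,1;1;1;1;1;1,0.0219,0.0721,0.128,0.077,0.179,18.8,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_01,box,1.545;1.404;1.094,0.109,1;1;1;1;1;1,0.0189,0.0458,0.201,0.121,0.281,10.8,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_02,box,3.063;1.712;1.721,0.096,1;1;1;1;1;1,0.0189,0.0546,0.156,0.094,0.218,13.2,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_03,elliptic_cylinder,0.981;0.951;1.668,0.067,1;0;0,0.0169,0.0441,0.181,0.109,0.253,8.2,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_04,box,3.111;2.638;2.147,0.097,1;1;1;1;1;1,0.0218,0.0664,0.144,0.086,0.202,14.2,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_05,box,1.615;1.068;1.328,0.056,1;1;1;1;1;1,0.0175,0.0503,0.157,0.094,0.22,16,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_06,box,1.68;0.758;1.078,0.105,1;1;1;1;1;1,0.0159,0.0449,0.161,0.097,0.225,10.7,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_07,box,3.312;2.24;2.824,0.065,1;1;1;1;1;1,0.0151,0.0361,0.205,0.123,0.287,16,0.16,0.42,0.04,0.04
pelvic_bones,pelvic_bones_08,elliptic_cylinder,2.465;1.208;2.51,0.099,1;0;0,0.0228,0.0527,0.215,0.129,0.301,13.4,0.16,0.42,0.04,0.04
sacrum,sacrum_01,box,1.526;0.71;1.133,0.035,1;1;1;1;1;1,0.0198,0.0574,0.155,0.093,0.217,2.3,0.16,0.42,0.04,0.04
sacrum,sacrum_02,elliptic_cylinder,0.827;1.002;1.073,0.034,1;0;0,0.0219,0.0696,0.135,0.081,0.189,2.4,0.16,0.42,0.04,0.04
sacrum,sacrum_03,box,1.127;0.766;0.594,0.026,1;1;1;1;1;1,0.0235,0.0675,0.157,0.094,0.22,2.7,0.16,0.42,0.04,0.04
sacrum,sacrum_04,box,0.808;0.806;0.467,0.024,1;1;1;1;1;1,0.0098,0.0318,0.131,0.079,0.183,3.3,0.16,0.42,0.04,0.04
sacrum,sacrum_05,elliptic_cylinder,1.144;0.84;1.262,0.023,1;0;0,0.0247,0.0637,0.184,0.11,0.258,2.1,0.16,0.42,0.04,0.04
sacrum,sacrum_06,elliptic_cylinder,0.845;1.014;1.511,0.042,1;0;0,0.014,0.043,0.142,0.085,0.199,2.7,0.16,0.42,0.04,0.04
sacrum,sacrum_07,box,1.068;1.001;0.76,0.019,1;1;1;1;1;1,0.0229,0.058,0.189,0.113,0.265,3.3,0.16,0.42,0.04,0.04
sacrum,sacrum_08,elliptic_cylinder,0.748;0.412;0.793,0.028,1;0;0,0.0153,0.044,0.157,0.094,0.22,3.3,0.16,0.42,0.04,0.04
sacrum,sacrum_09,box,1.199;1.15;1.044,0.034,1;1;1;1;1;1,0.0226,0.0641,0.16,0.096,0.224,2.8,0.16,0.42,0.04,0.04
sacrum,sacrum_10,elliptic_cylinder,1.017;0.741;1.171,0.037,1;0;0,0.0208,0.0547,0.179,0.107,0.251,3,0.16,0.42,0.04,0.04
femora_upper,femora_upper_01,box,4.294;3.626;2.007,0.138,1;1;1;1;1;1,0.0129,0.0256,0.265,0.159,0.371,52.8,0.16,0.42,0.04,0.04
femora_upper,femora_upper_02,elliptic_cylinder,1.784;1.55;3.005,0.122,1;0;0,0.0108,0.025,0.214,0.128,0.3,36.4,0.16,0.42,0.04,0.04
humeri_upper,humeri_upper_01,box,3.238;2.619;1.937,0.189,1;1;1;1;1;1,0.0182,0.0414,0.22,0.132,0.308,165.7,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_01,box,0.706;0.503;0.362,0.043,1;1;1;1;1;1,0.011,0.0323,0.152,0.091,0.213,7.3,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_02,box,1.061;0.942;0.994,0.074,1;1;1;1;1;1,0.0164,0.0534,0.13,0.078,0.182,6.6,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_03,deformed_cylinder,0.403;0.62;0.447;0.305;0.814,0.04,1;0;0,0.0223,0.0652,0.153,0.092,0.214,7.3,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_04,elliptic_cylinder,0.395;0.591;0.629,0.069,1;0;0,0.0225,0.0655,0.154,0.092,0.216,5.2,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_05,box,1.254;0.934;1.092,0.066,1;1;1;1;1;1,0.0133,0.044,0.127,0.076,0.178,7.1,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_06,elliptic_cylinder,1.117;0.585;1.184,0.079,1;0;0,0.0143,0.0424,0.15,0.09,0.21,6.5,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_07,elliptic_cylinder,0.809;0.683;1.364,0.055,1;0;0,0.0209,0.0709,0.122,0.073,0.171,4.4,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_08,box,1.078;0.794;0.865,0.045,1;1;1;1;1;1,0.0164,0.0486,0.15,0.09,0.21,4.5,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_09,deformed_cylinder,0.488;0.346;0.349;0.31;0.653,0.039,1;0;0,0.0136,0.0447,0.128,0.077,0.179,3.3,0.16,0.42,0.04,0.04
scapulae_ribs_clavicles,scapulae_ribs_clavicles_10,box,1.056;1.056;0.642,0.067,1;1;1;1;1;1,0.0221,0.0686,0.14,0.084,0.196,4.1,0.16,0.42,0.04,0.04
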