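table,group,observer,measurement,mad_cm,sd_cm,icc,ci_low,ci_high,sem_cm,cv_percent
per_observer,female,A,NLD,0.30,0.29,0.944,0.847,0.984,0.07,NA
per_observer,female,A,MLN_R,1.42,1.06,0.935,0.824,0.982,0.27,NA
per_observer,female,A,MLN_L,1.91,1.21,0.930,0.812,0.980,0.32,NA
per_observer,female,A,SNN_R,0.11,1.38,0.960,0.889,0.989,0.28,NA
per_observer,female,A,SNN_L,0.12,1.30,0.952,0.868,0.987,0.28,NA
per_observer,female,A,IMFLD,0.34,0.30,0.951,0.865,0.986,0.07,NA
per_observer,female,A,IMFML_R,0.39,0.99,0.935,0.824,0.982,0.25,NA
per_observer,female,A,IMFML_L,0.14,1.03,0.936,0.827,0.982,0.26,NA
per_observer,female,A,IMFN_R,0.32,1.25,0.843,0.617,0.954,0.50,NA
per_observer,female,A,IMFN_L,0.26,1.06,0.826,0.584,0.949,0.44,NA
per_observer,female,A,UPLD,0.57,1.44,0.905,0.752,0.973,0.45,NA
per_observer,female,A,UPN_R,0.58,1.18,0.992,0.977,0.998,0.11,NA
per_observer,female,A,UPN_L,0.70,1.22,0.993,0.980,0.998,0.10,NA
per_observer,female,B,NLD,0.41,0.31,0.988,0.965,0.997,0.03,NA
per_observer,female,B,MLN_R,1.71,1.08,0.970,0.915,0.992,0.19,NA
per_observer,female,B,MLN_L,1.61,1.03,0.958,0.883,0.988,0.21,NA
per_observer,female,B,SNN_R,0.15,1.07,0.977,0.935,0.994,0.16,NA
per_observer,female,B,SNN_L,0.14,0.94,0.969,0.913,0.991,0.17,NA
per_observer,female,B,IMFLD,0.29,0.24,0.962,0.894,0.990,0.05,NA
per_observer,female,B,IMFML_R,0.26,1.04,0.926,0.802,0.979,0.28,NA
per_observer,female,B,IMFML_L,0.50,1.31,0.985,0.957,0.996,0.16,NA
per_observer,female,B,IMFN_R,0.53,1.51,0.948,0.857,0.986,0.34,NA
per_observer,female,B,IMFN_L,0.05,1.08,0.955,0.875,0.988,0.23,NA
per_observer,female,B,UPLD,0.70,1.33,0.932,0.817,0.981,0.35,NA
per_observer,female,B,UPN_R,0.68,1.00,0.988,0.965,0.997,0.11,NA
per_observer,female,B,UPN_L,1.00,1.04,0.983,0.951,0.995,0.14,NA
per_observer,male,A,NLD,0.36,0.20,0.887,0.711,0.968,0.07,NA
per_observer,male,A,MLN_R,0.47,0.46,0.986,0.960,0.996,0.05,NA
per_observer,male,A,MLN_L,0.21,0.40,0.984,0.954,0.996,0.05,NA
per_observer,male,A,SNN_R,0.89,0.84,0.973,0.924,0.993,0.14,NA
per_observer,male,A,SNN_L,0.74,0.77,0.973,0.924,0.993,0.13,NA
per_observer,male,A,IMFLD,0.27,0.22,0.909,0.761,0.974,0.07,NA
per_observer,male,A,IMFML_R,0.32,0.50,0.987,0.963,0.996,0.06,NA
per_observer,male,A,IMFML_L,0.09,0.59,0.972,0.921,0.992,0.10,NA
per_observer,male,A,IMFN_R,0.15,0.34,0.988,0.965,0.997,0.04,NA
per_observer,male,A,IMFN_L,0.37,0.38,0.979,0.940,0.994,0.06,NA
per_observer,male,A,UPLD,0.16,0.35,0.963,0.897,0.990,0.07,NA
per_observer,male,A,UPN_R,0.11,0.34,0.991,0.974,0.998,0.03,NA
per_observer,male,A,UPN_L,0.14,0.32,0.996,0.988,0.999,0.02,NA
per_observer,male,B,NLD,0.31,0.18,0.953,0.870,0.987,0.04,NA
per_observer,male,B,MLN_R,0.62,0.47,0.996,0.988,0.999,0.03,NA
per_observer,male,B,MLN_L,0.33,0.39,0.994,0.983,0.998,0.03,NA
per_observer,male,B,SNN_R,1.12,0.75,0.994,0.983,0.998,0.06,NA
per_observer,male,B,SNN_L,0.90,0.68,0.991,0.974,0.998,0.06,NA
per_observer,male,B,IMFLD,0.26,0.22,0.950,0.862,0.986,0.05,NA
per_observer,male,B,IMFML_R,0.27,0.43,0.993,0.980,0.998,0.04,NA
per_observer,male,B,IMFML_L,0.07,0.54,0.976,0.932,0.993,0.08,NA
per_observer,male,B,IMFN_R,0.23,0.34,0.990,0.971,0.997,0.03,NA
per_observer,male,B,IMFN_L,0.41,0.41,0.997,0.991,0.999,0.02,NA
per_observer,male,B,UPLD,0.27,0.29,0.959,0.886,0.989,0.06,NA
per_observer,male,B,UPN_R,0.20,0.28,0.998,0.994,0.999,0.01,NA
per_observer,male,B,UPN_L,0.29,0.31,0.999,0.997,1.000,0.01,NA
inter_rater,female,NA,NLD,NA,NA,0.968,0.910,0.991,0.01,5.7
inter_rater,female,NA,MLN_R,NA,NA,0.968,0.910,0.991,0.02,1.2
inter_rater,female,NA,MLN_L,NA,NA,0.924,0.797,0.979,0.00,0.1
inter_rater,female,NA,SNN_R,NA,NA,0.989,0.968,0.997,0.00,0.1
inter_rater,female,NA,SNN_L,NA,NA,0.986,0.960,0.996,0.00,0.0
inter_rater,female,NA,IMFLD,NA,NA,0.909,0.761,0.974,0.01,5.8
inter_rater,female,NA,IMFML_R,NA,NA,0.953,0.870,0.987,0.04,2.2
inter_rater,female,NA,IMFML_L,NA,NA,0.858,0.648,0.959,0.11,3.0
inter_rater,female,NA,IMFN_R,NA,NA,0.810,0.553,0.943,0.15,4.5
inter_rater,female,NA,IMFN_L,NA,NA,0.898,0.736,0.971,0.04,1.2
inter_rater,female,NA,UPLD,NA,NA,0.944,0.847,0.984,0.09,4.9
inter_rater,female,NA,UPN_R,NA,NA,0.987,0.963,0.996,0.02,2.3
inter_rater,female,NA,UPN_L,NA,NA,0.952,0.868,0.987,0.08,3.8
inter_rater,male,NA,NLD,NA,NA,0.943,0.844,0.984,0.01,6.3
inter_rater,male,NA,MLN_R,NA,NA,0.996,0.988,0.999,0.00,0.7
inter_rater,male,NA,MLN_L,NA,NA,0.998,0.994,0.999,0.00,0.5
inter_rater,male,NA,SNN_R,NA,NA,0.996,0.988,0.999,0.01,0.6
inter_rater,male,NA,SNN_L,NA,NA,0.997,0.991,0.999,0.00,0.4
inter_rater,male,NA,IMFLD,NA,NA,0.957,0.881,0.988,0.00,0.4
inter_rater,male,NA,IMFML_R,NA,NA,0.992,0.977,0.998,0.00,0.2
inter_rater,male,NA,IMFML_L,NA,NA,0.995,0.985,0.999,0.00,0.1
inter_rater,male,NA,IMFN_R,NA,NA,0.998,0.994,0.999,0.00,0.9
inter_rater,male,NA,IMFN_L,NA,NA,0.995,0.985,0.999,0.01,0.9
inter_rater,male,NA,UPLD,NA,NA,0.967,0.907,0.991,0.00,0.5
inter_rater,male,NA,UPN_R,NA,NA,0.998,0.994,0.999,0.00,0.6
inter_rater,male,NA,UPN_L,NA,NA,0.999,0.997,1.000,0.00,1.0
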