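age_label,bw_mean,bw_sd,diam_mean,diam_sd,septum_mean,septum_sd,vl_mean,vl_sd,va_mean,va_sd,sa_mean,sa_sd
13dpc,NA,NA,NA,NA,NA,NA,0.53,0.14,NA,NA,NA,NA
neonate,0.13,0.00,349,55,41,1,2.15,0.53,0.96,0.41,43.26,3.44
4dpn,0.21,0.00,258,1,34,0,4.46,0.33,1.79,0.19,98.51,9.67
7dpn,0.28,0.01,192,6,24,2,5.60,0.05,2.26,0.04,168.02,21.01
11dpn,0.62,0.15,141,7,25,2,18.95,3.58,5.12,0.69,272.92,45.08
14dpn,1.00,0.03,126,14,26,2,25.76,1.75,9.94,2.19,492.31,180.20
21dpn,2.34,0.09,108,8,18,4,60.47,9.96,22.80,1.66,1284.46,442.56
28dpn,4.19,0.04,89,13,20,0,199.19,13.34,72.74,5.59,3623.40,75.21
35dpn,7.00,0.83,70,13,16,5,408.76,76.85,157.50,23.76,9068.70,1271.31
49dpn,12.11,1.35,52,6,12,4,455.22,47.59,225.07,20.18,15301.91,1497.83
57dpn,21.64,8.81,51,10,10,2,877.06,267.17,359.21,11.18,21823.37,2809.74
adult,74.38,11.22,79,17,10,1,2629.33,320.77,1232.84,275.57,38573.16,6275.27
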