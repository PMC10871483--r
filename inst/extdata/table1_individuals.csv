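specimen_id,age_label,medium,staining,bw_g,diam_um,diam_sd,septum_um,septum_sd,vl_mm3,va_mm3,sa_mm2
2095d,13dpc,A.,,NA,NA,NA,NA,NA,0.63,NA,NA
2095e,13dpc,K.,PTA,NA,NA,NA,NA,NA,0.48,NA,NA
2095f,13dpc,A.,,NA,NA,NA,NA,NA,0.36,NA,NA
2095g,13dpc,K.,PTA,NA,NA,NA,NA,NA,0.66,NA,NA
2350_1,neonate,K.,PTA,0.13,294,70,42,11,1.73,0.57,42.68
2350_3,neonate,K.,PTA,0.13,351,97,40,11,1.98,0.91,40.14
2350_7,neonate,K.,PTA,0.13,403,87,41,13,2.74,1.39,46.95
2257_4,4dpn,A.,,0.21,259,51,33,10,4.35,1.74,100.99
2257_6,4dpn,K.,PTA,0.21,258,76,34,9,4.19,1.64,87.85
2257_3,4dpn,A.,,0.21,257,77,34,12,4.83,2.00,106.70
2383_2,7dpn,K.,PTA,0.28,196,57,25,11,5.63,2.29,153.16
2383_4,7dpn,A.,,0.27,187,80,22,8,5.56,2.23,182.87
1993_2,11dpn,E.,Iodid,0.69,148,38,25,7,20.58,4.68,273.14
2419_3,11dpn,A.,,0.45,140,46,26,10,14.84,5.92,227.73
1993_3,11dpn,A.,,0.73,135,40,23,10,21.42,4.77,317.88
1994_8,14dpn,E.,PTA,0.99,132,30,26,6,27.78,9.98,409.45
1994_9,14dpn,E.,PTA,0.98,137,28,27,5,24.87,12.11,699.04
1994_10,14dpn,E.,PTA,1.03,110,28,24,7,24.64,7.72,368.44
2040,21dpn,E.,PTA,2.43,106,23,23,3,71.14,20.88,877.41
2037,21dpn,A.,,2.34,116,29,16,4,58.84,23.84,1220.42
2036,21dpn,A.,,2.26,101,26,16,4,51.42,23.68,1755.55
2059,28dpn,E.,PTA,4.22,80,14,19,5,208.62,68.79,3570.22
2060,28dpn,E.,Iodid,4.16,98,18,20,5,189.75,76.69,3676.58
2065,35dpn,E.,Iodid,7.25,85,18,17,5,388.59,143.07,9606.84
2405,35dpn,K.,PTA,6.08,61,15,10,3,344.00,144.51,7616.83
2194,35dpn,K.,PTA,7.68,64,16,20,4,493.68,184.93,9982.44
2049,49dpn,E.,Iodid,13.64,58,10,16,4,504.03,201.78,13703.22
2402,49dpn,K.,PTA,11.59,50,12,9,2,452.65,237.29,15529.72
2403,49dpn,K.,PTA,11.09,47,11,10,2,408.96,236.15,16672.78
2179,57dpn,E.,Iodid,31.58,63,11,9,2,1176.68,372.105,18896.72
2413,57dpn,K.,PTA,14.81,44,9,9,2,663.60,353.06,22073.97
2416,57dpn,K.,PTA,18.53,47,9,12,2,790.89,352.45,24499.42
2095,adult,K.,PTA,87.22,61,15,11,3,2948.94,1396.63,43744.40
2117,adult,K.,PTA,69.47,81,16,10,3,2307.41,914.69,31591.77
2419,adult,K.,PTA,66.46,94,20,10,3,2631.63,1387.20,40383.30
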