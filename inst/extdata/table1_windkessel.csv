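patient,outlet,R1_pa_s_per_m3,R2_pa_s_per_m3,C_m3_per_pa
Patient-1,BT,2.82E+07,1.88E+08,1.41E-06
Patient-1,LCC,9.17E+07,3.97E+08,1.72E-06
Patient-1,LSA,7.28E+07,3.45E+08,1.64E-06
Patient-1,DA,7.72E+06,5.60E+07,1.18E-06
Patient-2,BT,7.605E+06,3.814E+08,2.278E-07
Patient-2,LCC,2.800E+06,1.263E+09,5.239E-07
Patient-2,LSA,2.806E+06,8.201E+08,5.513E-07
Patient-2,DA,1.943E+05,1.560E+08,5.019E-07
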