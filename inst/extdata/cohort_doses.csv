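patient_id,age_years,sex,tumor_site,administered_activity_GBq,tumor_volume_mL,grade_thrombocytopenia,grade_leucopenia,ad_tumor_3d_Gy,ad_rbm_3d_Gy,ad_tumor_sphere_Gy,ad_rbm_blood_Gy,ad_rbm_cranium_Gy
7,63,F,Rectum,6.2,14,0,0,0.73,0.39,0.71,,
10,70,M,Liver,7.4,70,4,1,2.94,0.51,2.67,,
11,55,F,Liver,7.4,44,0,0,2.53,0.29,2.47,,
12,70,M,Liver,7.4,386,0,0,1.54,0.30,1.47,,
13,76,M,Colon,7.4,23,0,0,0.51,0.12,0.51,,
14,52,F,Liver,4.0,23,1,0,3.70,0.70,3.72,,
15,58,M,Liver,5.9,285,1,0,0.86,0.58,0.83,,
16,76,M,Colon,4.6,121,3,2,0.66,0.97,0.64,,
17,73,M,Lung,4.5,65,2,0,0.63,0.43,0.62,,
18,63,F,Liver,2.5,104,0,2,4.52,0.47,4.44,,
19,66,F,Liver,7.4,141,0,0,1.45,0.28,1.38,,
20,72,M,Lung,5.6,723,1,0,0.46,0.72,0.45,,
21,39,F,Liver,5.6,154,0,0,2.47,0.23,2.45,,
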