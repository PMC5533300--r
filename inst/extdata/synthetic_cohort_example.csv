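id,study,sex,menopausal_status,age,weight_kg,bmi,iron_intake_mg_d,iron_meat_mg_d,sf_ug_l,hb_g_dl,crp_mg_l,act_g_l,iron_supplement
synthetic-premenopausal-0001,synthetic,female,premenopausal,28.29,66.93,35.33,9.27,2.82,50.99,13.54,6.4,,false
synthetic-premenopausal-0002,synthetic,female,premenopausal,37.09,41.21,34.99,13.55,3.25,15.3,13.92,2.41,,false
synthetic-premenopausal-0003,synthetic,female,premenopausal,41.48,51.06,27.79,7.89,1.53,25.44,11.92,3.82,,false
synthetic-premenopausal-0004,synthetic,female,premenopausal,22.6,64.77,26.76,8.27,1.65,31.77,13.2,3.64,,false
synthetic-premenopausal-0005,synthetic,female,premenopausal,39.02,63.12,31.04,21.88,4.08,170.96,13.67,8.02,,false
synthetic-premenopausal-0006,synthetic,female,premenopausal,19.37,68.97,35.36,9.74,1.49,30.09,13.31,1.93,,true
synthetic-premenopausal-0007,synthetic,female,premenopausal,48.22,80.96,28.71,20.45,3.64,16.87,12.51,4.29,,false
synthetic-premenopausal-0008,synthetic,female,premenopausal,27.2,76.21,27.8,7.93,0.99,32.39,12.39,3.26,,false
synthetic-premenopausal-0009,synthetic,female,premenopausal,49.44,44.14,14,5.09,0.45,66.65,13.66,12.69,,false
synthetic-premenopausal-0010,synthetic,female,premenopausal,31.32,75.35,28.97,14.28,2.67,76.76,12.47,1.41,,false
synthetic-premenopausal-0011,synthetic,female,premenopausal,36.82,66.11,25.62,9.59,1.27,131.07,13.67,6.24,,false
synthetic-premenopausal-0012,synthetic,female,premenopausal,23.92,35,27.53,9.38,1.31,43.2,11.53,2.9,,false
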