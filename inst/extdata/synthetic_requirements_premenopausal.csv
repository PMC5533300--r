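# synthetic lognormal template (median 1.41 mg/d, 97.5th 3.15 mg/d)
percentile,requirement_mg_d
2.5,0.631
5,0.718
10,0.834
25,1.069
50,1.41
75,1.859
90,2.385
95,2.768
97.5,3.15
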