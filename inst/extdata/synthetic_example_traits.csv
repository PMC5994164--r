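"species","density","response","role"
"fossil_A",0.04786,NA,"target"
"extant_01",0.1716,21.47,"training"
"extant_02",0.2649,21.9,"training"
"fossil_B",0.3444,NA,"target"
"extant_03",0.1829,12.17,"training"
"extant_04",0.07874,9.902,"training"
"fossil_C",0.2563,NA,"target"
"extant_05",0.2526,48.56,"training"
"fossil_D",0.1094,NA,"target"
"extant_06",0.07861,29.87,"training"
"extant_07",0.2729,0.9704,"training"
"extant_08",0.3861,4.237,"training"
"extant_09",0.03287,1.289,"training"
"extant_10",0.02029,0.7373,"training"
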