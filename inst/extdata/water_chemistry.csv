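# Water chemistry, bulk carbon and solid-phase extraction efficiency for the
# two Baltic Sea reference samples and 18 deep-borehole sampling occasions.
# Transcribed from the published survey table; concentrations in mg/L,
# conductivity in mS/m, extraction efficiency in % of DOC.
borehole,water_type,date,n,conductivity,ph,alkalinity,ca,mg,cl,so4,doc,doc_sd,tdn,tdn_sd,extraction_efficiency
LMO,Baltic Sea,04-19,2,1230,7.98,98.9,102,245,3860,515,3.79,0.07,0.24,0.01,63
Aspo,Baltic Sea,04-19,2,980,7.32,75.4,82.9,190,3000,435,7.05,0.06,0.43,0.01,68
SA1229A_1,BrMarine1,11-18,1,1031,7.25,252.6,334,146,3282,266,5.81,0.21,5.62,0.16,74
SA1229A_1,BrMarine1,04-19,1,1030,7.28,249,345,140,3270,259,5.84,0.07,5.52,0.10,75
KA2051A01_5,BrMarine1,03-19,2,677,7.69,155,368,45.7,2050,181,6.20,0.09,0.33,0.01,79
KA2511A_5,BrMarine1,03-19,2,1000,7.54,154,471,81.3,3200,300,4.47,0.04,0.69,0.01,76
KA3105A_3,BrMarine2,11-18,1,871,7.50,127.6,455,72.3,2747,274,4.58,0.13,0.38,0.00,78
KA3105A_3,BrMarine2,03-19,1,868,7.72,121,463,69,2770,261,4.44,0.05,0.38,0.02,82
KA3600F_2,BrMarine2,11-18,1,1197,7.47,126.6,708,75.2,3884,299,3.97,0.03,0.45,0.02,79
KA3600F_2,BrMarine2,03-19,1,1190,7.49,126,714,72.6,3960,293,3.85,0.03,0.44,0.03,78
KA2865A01_1,Transition,03-19,2,1960,7.38,78.7,2090,56.3,7110,350,2.94,0.02,0.29,0.02,78
KA3385A_1,Transition,03-19,2,2060,7.48,25.1,2220,55.4,7480,399,1.17,0.02,0.13,0.01,87
KA3510A_2,Transition,03-19,2,2060,7.75,11.5,2280,32.4,7340,488,1.41,0.04,0.10,0.01,81
SA2600A_1,Saline,11-18,1,3404,7.53,16.4,4400,33.7,13230,596,0.90,0.05,0.11,0.02,87
SA2600A_1,Saline,03-19,1,3410,7.50,16.6,4620,32.1,13000,606,0.95,0.04,0.10,0.01,82
HA2780A_1,Saline,03-19,2,3860,7.81,9.1,5590,32.8,15300,644,0.85,0.04,0.08,0.01,83
SA1730A_1,Saline,11-18,1,3700,7.66,12.6,5050,31.6,14540,615,0.78,0.01,0.09,0.01,88
SA1730A_1,Saline,03-19,1,3640,7.60,15.8,5100,29.4,14600,623,0.98,0.01,0.09,0.01,82
KA1755A_3,Saline,03-19,2,3380,7.61,9.3,4790,30.5,12900,592,0.76,0.04,0.08,0.02,79
KA2862A_1,Saline,03-19,2,4140,7.65,8.5,6120,33,16200,595,0.92,0.04,0.08,0.02,82
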