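"subgroup","pfs_hr","pfs_lo","pfs_hi","os_hr","os_lo","os_hi"
"Male",0.69,0.51,0.92,0.45,0.31,0.64
"Female",0.7,0.48,1.01,0.6,0.39,0.92
"Age < 64 yr",0.72,0.52,1,0.54,0.37,0.8
"Age >= 64 yr",0.71,0.51,0.98,0.48,0.32,0.73
"BRAF mutant",1.01,0.66,1.56,0.73,0.43,1.26
"NRAS mutant",0.62,0.36,1.07,0.48,0.25,0.91
"BRAF & NRAS WT",0.58,0.42,0.81,0.46,0.31,0.69
"ECOG PS 0",0.68,0.49,0.95,0.47,0.31,0.72
"ECOG PS >= 1",0.99,0.7,1.42,0.82,0.56,1.21
"Stage III/M1A/M1B",0.74,0.48,1.15,0.53,0.3,0.93
"Stage M1C/M1D",0.68,0.51,0.89,0.5,0.37,0.69
"Brain metastases: no",0.79,0.52,1.18,0.51,0.31,0.82
"Brain metastases: yes",0.64,0.48,0.84,0.47,0.33,0.66
"Lung metastases: no",0.73,0.54,0.98,0.54,0.38,0.78
"Lung metastases: yes",0.69,0.48,1,0.48,0.31,0.74
"Liver metastases: no",0.68,0.45,1.04,0.59,0.37,0.93
"Liver metastases: yes",0.71,0.54,0.94,0.48,0.34,0.67
"LDH = UNL",0.75,0.54,1.02,0.45,0.3,0.69
"LDH > UNL",0.56,0.38,0.83,0.47,0.3,0.72
"PD-(L)1 setting: adjuvant",0.52,0.22,1.25,0.81,0.17,3.9
"PD-(L)1 setting: metastatic",0.74,0.58,0.94,0.54,0.4,0.71
"Resistance: innate",0.75,0.56,0.99,0.52,0.37,0.71
"Resistance: acquired",0.71,0.44,1.14,0.56,0.31,1.01
"Best response to PD-(L)1: SD/PD",0.72,0.55,0.95,0.5,0.36,0.68
"Best response to PD-(L)1: CR/PR",0.79,0.45,1.4,0.7,0.34,1.43
"Best response to PD-(L)1: not applicable",0.52,0.22,1.25,0.81,0.17,3.9
"Time to progression <= 3 mo",0.63,0.46,0.87,0.45,0.31,0.64
"Time to progression > 3 mo",0.75,0.53,1.05,0.52,0.34,0.81
"Time from PD-(L)1 <= 1 mo",0.72,0.52,0.99,0.54,0.37,0.8
"Time from PD-(L)1 > 1 mo",0.69,0.49,0.96,0.47,0.31,0.7
"Interim systemic treatment: no",0.67,0.52,0.87,0.51,0.38,0.69
"Interim systemic treatment: yes",0.68,0.36,1.3,0.34,0.16,0.75
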