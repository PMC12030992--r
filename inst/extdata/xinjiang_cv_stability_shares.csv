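grade,p2000_2006,p2007_2012,p2013_2018,p2019_2024,change,mean
Extremely insignificant,62.91,53.57,53.56,37.51,-25.39,48.67
Insignificant,22.55,27.52,27.83,32.20,9.64,33.50
Moderate,6.53,9.24,8.48,15.25,8.72,8.73
Significant,3.37,4.69,4.81,7.72,4.35,4.51
Extremely significant,4.65,4.98,5.31,7.32,2.68,4.59
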