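grade,y2000,y2006,y2012,y2018,y2024,change
Lowest,53.91,52.30,48.47,52.15,52.89,-1.03
Low,25.61,26.61,28.74,25.15,23.93,-1.68
Medium,6.42,6.46,7.15,6.82,6.78,0.36
High,4.25,4.35,4.69,4.71,4.80,0.55
Highest,9.80,10.28,10.96,11.18,11.60,1.80
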