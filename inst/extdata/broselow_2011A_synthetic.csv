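# SYNTHETIC Broselow 2011A calibration fixture (non-clinical)
segment_lower_cm,segment_upper_cm,weight_kg,edition
50,55,5.1,2011A
55,60,6,2011A
60,65,7,2011A
65,70,8,2011A
70,75,9.1,2011A
75,80,10.2,2011A
80,85,11.4,2011A
85,90,12.6,2011A
90,95,13.9,2011A
95,100,15.3,2011A
100,105,16.7,2011A
105,110,18.2,2011A
110,115,19.7,2011A
115,120,21.2,2011A
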