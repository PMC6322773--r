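# SYNTHETIC Broselow 2007B calibration fixture (non-clinical)
segment_lower_cm,segment_upper_cm,weight_kg,edition
50,55,4.8,2007B
55,60,5.7,2007B
60,65,6.6,2007B
65,70,7.5,2007B
70,75,8.6,2007B
75,80,9.6,2007B
80,85,10.7,2007B
85,90,11.9,2007B
90,95,13.1,2007B
95,100,14.4,2007B
100,105,15.7,2007B
105,110,17.1,2007B
110,115,18.5,2007B
115,120,20,2007B
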