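# SYNTHETIC Ralston three-tape calibration fixture (non-clinical)
band,segment_lower_cm,segment_upper_cm,weight_kg
severe,50,55,3.9
severe,55,60,4.5
severe,60,65,5.2
severe,65,70,6
severe,70,75,6.8
severe,75,80,7.7
severe,80,85,8.5
severe,85,90,9.5
severe,90,95,10.4
severe,95,100,11.5
severe,100,105,12.5
severe,105,110,13.6
severe,110,115,14.7
severe,115,120,15.9
moderate,50,55,4.4
moderate,55,60,5.1
moderate,60,65,5.9
moderate,65,70,6.8
moderate,70,75,7.7
moderate,75,80,8.6
moderate,80,85,9.6
moderate,85,90,10.7
moderate,90,95,11.8
moderate,95,100,12.9
moderate,100,105,14.1
moderate,105,110,15.4
moderate,110,115,16.6
moderate,115,120,18
normal,50,55,4.9
normal,55,60,5.8
normal,60,65,6.7
normal,65,70,7.7
normal,70,75,8.7
normal,75,80,9.8
normal,80,85,11
normal,85,90,12.1
normal,90,95,13.4
normal,95,100,14.7
normal,100,105,16.1
normal,105,110,17.5
normal,110,115,18.9
normal,115,120,20.4
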