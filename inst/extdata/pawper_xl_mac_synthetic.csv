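# SYNTHETIC PAWPER XL-MAC calibration fixture (non-clinical)
segment_lower_cm,segment_upper_cm,cutoffs_cm,weights_kg
55,57.5,12.0;12.8;13.6;14.5;15.3;16.1,4.3;4.7;5.1;5.6;6.1;6.7;7.4
57.5,60,12.0;12.8;13.6;14.5;15.3;16.2,4.7;5.1;5.5;6.0;6.6;7.3;8.0
60,62.5,12.0;12.8;13.7;14.5;15.3;16.2,5.0;5.4;5.9;6.5;7.1;7.8;8.6
62.5,65,12.0;12.9;13.7;14.5;15.4;16.2,5.4;5.8;6.4;7.0;7.6;8.4;9.2
65,67.5,12.1;12.9;13.7;14.6;15.4;16.2,5.7;6.3;6.8;7.4;8.2;9.0;9.9
67.5,70,12.1;12.9;13.8;14.6;15.4;16.3,6.1;6.7;7.3;7.9;8.7;9.6;10.6
70,72.5,12.1;12.9;13.8;14.6;15.5;16.3,6.5;7.1;7.7;8.5;9.3;10.2;11.2
72.5,75,12.1;13.0;13.8;14.7;15.5;16.3,6.9;7.5;8.2;9.0;9.9;10.8;11.9
75,77.5,12.2;13.0;13.9;14.7;15.5;16.4,7.4;8.0;8.7;9.5;10.5;11.5;12.7
77.5,80,12.2;13.1;13.9;14.7;15.6;16.4,7.8;8.5;9.2;10.1;11.1;12.2;13.4
80,82.5,12.3;13.1;13.9;14.8;15.6;16.4,8.2;9.0;9.8;10.7;11.7;12.8;14.2
82.5,85,12.3;13.2;14.0;14.8;15.7;16.5,8.7;9.4;10.3;11.2;12.3;13.6;14.9
85,87.5,12.4;13.2;14.0;14.9;15.7;16.5,9.1;9.9;10.8;11.8;13.0;14.3;15.7
87.5,90,12.4;13.3;14.1;14.9;15.8;16.6,9.6;10.5;11.4;12.5;13.7;15.0;16.6
90,92.5,12.5;13.3;14.2;15.0;15.8;16.7,10.1;11.0;12.0;13.1;14.3;15.8;17.4
92.5,95,12.6;13.4;14.2;15.1;15.9;16.7,10.6;11.5;12.6;13.7;15.0;16.5;18.2
95,97.5,12.6;13.5;14.3;15.1;16.0;16.8,11.1;12.1;13.1;14.4;15.7;17.3;19.1
97.5,100,12.7;13.6;14.4;15.2;16.1;16.9,11.6;12.6;13.8;15.0;16.5;18.1;20.0
100,102.5,12.8;13.6;14.5;15.3;16.2;17.0,12.1;13.2;14.4;15.7;17.2;18.9;20.9
102.5,105,12.9;13.7;14.6;15.4;16.2;17.1,12.7;13.8;15.0;16.4;18.0;19.8;21.8
105,107.5,13.0;13.9;14.7;15.5;16.4;17.2,13.2;14.4;15.6;17.1;18.7;20.6;22.7
107.5,110,13.1;14.0;14.8;15.6;16.5;17.3,13.8;15.0;16.3;17.8;19.5;21.5;23.7
110,112.5,13.2;14.1;14.9;15.7;16.6;17.4,14.3;15.6;17.0;18.5;20.3;22.3;24.6
112.5,115,13.2;14.1;14.9;15.7;16.6;17.4,14.9;16.2;17.6;19.3;21.1;23.2;25.6
115,117.5,13.2;14.1;14.9;15.7;16.6;17.4,15.5;16.8;18.3;20.0;22.0;24.1;26.6
117.5,120,13.2;14.1;14.9;15.7;16.6;17.4,16.1;17.5;19.0;20.8;22.8;25.1;27.6
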