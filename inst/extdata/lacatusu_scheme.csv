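lower,upper,label,rank
0,0.10,Very slight contamination,1
0.10,0.25,Slight contamination,2
0.26,0.5,Moderate contamination,3
0.51,0.75,Severe contamination,4
0.76,1.00,Very severe contamination,5
1.10,2.0,Slight pollution,6
2.1,4.0,Moderate pollution,7
4.1,9.0,Severe pollution,8
9.1,16.0,Very severe pollution,9
16.0,,Excessive pollution,10
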