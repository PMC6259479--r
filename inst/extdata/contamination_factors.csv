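site_id,parameter,cf
S1,Pb,2.9
S1,Hg,1.7
S1,Cd,2.0
S1,Cu,5.1
S1,Zn,9.2
S2,Pb,3.2
S2,Hg,1.7
S2,Cd,2.8
S2,Cu,7.1
S2,Zn,8.6
S3,Pb,3.9
S3,Hg,2.3
S3,Cd,3.7
S3,Cu,3.7
S3,Zn,2.7
S4,Pb,4.3
S4,Hg,1.8
S4,Cd,2.5
S4,Cu,5.2
S4,Zn,0.8
S5,Pb,2.6
S5,Hg,2.9
S5,Cd,5.7
S5,Cu,21.1
S5,Zn,30.0
S6,Pb,3.1
S6,Hg,3.1
S6,Cd,4.2
S6,Cu,12.6
S6,Zn,20.9
S7,Pb,3.6
S7,Hg,2.1
S7,Cd,9.4
S7,Cu,17.9
S7,Zn,32.5
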