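patient,age_years,sex,side,total_fragments,included_fragments,ao_class
1,31,m,R,4,3,2R3C
2,60,m,L,4,3,2R3C
3,46,f,L,7,6,2R3C
4,53,f,L,2,2,2R3C
5,34,f,R,3,3,2R3C
6,29,f,L,1,1,2R3A
7,20,f,R,3,2,2R3C
8,15,f,R,3,2,2R3C
9,48,f,L,3,2,2R3C
10,50,f,R,2,1,2R3A
11,28,m,L,2,2,2R3B
12,67,m,R,3,2,2R3C
13,45,m,R,2,2,2R3B
14,40,m,L,2,2,2R3B
15,23,f,R,1,1,2R3B
16,23,f,L,3,2,2R3C
17,55,m,L,7,4,2R3C
18,66,m,R,3,3,2R3C
19,51,m,R,3,3,2R3C
20,51,m,L,5,5,2R3C
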