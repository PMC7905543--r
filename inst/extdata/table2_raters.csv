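rater_id,profession,clinical_years,planning_years
1,SS,24,10
2,BE,,2.0
3,BE,,3.0
4,SOR,6.0,1.5
5,SOR,6.0,1.0
6,SOR,7.0,0.0
7,JOR,1.5,0.0
8,JOR,3.0,0.0
9,JOR,1.5,0.0
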