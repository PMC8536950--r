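age_lo,age_hi,sex,annual_q
55,60,female,0.00439183920317657
60,65,female,0.00688777493905525
65,70,female,0.0108021813678342
70,75,female,0.0169411926690492
75,80,female,0.0265690788996065
80,85,female,0.0416686101955026
85,90,female,0.0653493891220467
90,95,female,0.102488243274444
95,100,female,0.160733560796792
100,105,female,0.252080402014834
55,60,male,0.00638812975007502
60,65,male,0.0100185817295349
65,70,male,0.0157122638077588
70,75,male,0.0246417347913442
75,80,male,0.0386459329448822
80,85,male,0.0606088875570948
85,90,male,0.0950536569047952
90,95,male,0.149073808399192
95,100,male,0.23379427024988
100,105,male,0.366662402930668
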