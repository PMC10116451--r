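district,AAAAA,AAAA,AAA,AA,A
Xuanwu,0,532,1352,150,0
Qinhuai,0,1596,1352,525,175
Gulou,0,1862,2535,225,175
Liuhe,0,266,507,75,35
Jianye,778,532,676,0,70
Yuhuatai,0,532,1690,150,140
Qixia,1556,1064,169,675,245
Pukou,778,266,507,450,35
Jiangning,1556,1596,1352,150,280
Lishui,0,266,676,75,35
Gaochun,0,266,0,0,0
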