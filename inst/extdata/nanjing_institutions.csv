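district,AAAAA,AAAA,AAA,AA,A
Xuanwu,0,2,8,2,0
Qinhuai,0,6,8,7,5
Gulou,0,7,15,3,5
Liuhe,0,1,3,1,1
Jianye,1,2,4,0,2
Yuhuatai,0,2,10,2,4
Qixia,2,4,1,9,7
Pukou,1,1,3,6,1
Jiangning,2,6,8,2,8
Lishui,0,1,4,1,1
Gaochun,0,1,0,0,0
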