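schedule,cycle,beds_per_1000
original,1,48
original,2,51
original,3,54
original,4,57
original,5,60
existing,1,48
existing,2,51
existing,3,55
existing,4,59
existing,5,63
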