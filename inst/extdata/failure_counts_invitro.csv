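scenario,large_aff,small_aff,large_epjf,small_epjf,total_score
case1,6,0,6,0,12
case2,4,0,3,3,8.5
case3,4,1,3,0,7.5
case4,1,4,1,1,4.5
case5,0,0,0,0,0
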