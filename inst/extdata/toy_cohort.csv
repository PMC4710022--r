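id,time,cause,group,selected,pi
1,1,1,a,1,1
2,2,2,a,1,1
3,3,0,b,1,1
4,4,1,b,1,1
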