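"src","dst","nu","p","tau"
1,2,NA,2,0.5
2,3,NA,2,1
2,4,NA,2,1
3,5,NA,2,1
4,5,NA,2,1
5,6,NA,2,0.5
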