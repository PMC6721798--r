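construct,mean,sd,n
FTL,1,0,6
D3RE,4.4,0.4,6
LOOP,12.5,2.9,6
DOUBLE,41.8,6.5,6
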