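"name","vertex","x","y"
"factory_1",1,12,26
"factory_2",1,28,30
"railway",1,0,20
"railway",2,40,24
"G216",1,18,0
"G216",2,22,40
"S11",1,0,8
"S11",2,40,4
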