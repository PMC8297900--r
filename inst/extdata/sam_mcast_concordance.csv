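"","B","A","C","D"
"B",39,2,1,0
"A",0,2,1,0
"C",2,0,8,0
"D",2,0,0,4
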