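"kind","label","start","end"
"cuff_inflation","",2,2.5
"intervention","rest",5,9
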