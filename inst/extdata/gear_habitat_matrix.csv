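gear,reef,fad,deep,shore,mangrove
gill_net,TRUE,FALSE,TRUE,TRUE,TRUE
seine_net,TRUE,TRUE,TRUE,TRUE,FALSE
beach_seine,FALSE,FALSE,FALSE,TRUE,FALSE
hand_line,TRUE,TRUE,TRUE,TRUE,FALSE
long_line,TRUE,TRUE,TRUE,FALSE,FALSE
spearfishing,TRUE,FALSE,FALSE,TRUE,TRUE
trap,TRUE,FALSE,TRUE,FALSE,TRUE
gleaning,TRUE,FALSE,FALSE,TRUE,TRUE
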