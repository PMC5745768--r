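group,CFL20,CFL30,CFL40,CFL50,CFL2
male,7,13,18,13,0
female,7,9,11,2,1
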