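group,CFL20,CFL30,CFL40,CFL50,CFL2
right,5,9,15,8,0
left,7,11,11,7,1
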