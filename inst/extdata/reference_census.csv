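category,n
CFL20,14
CFL30,22
CFL40,29
CFL50,15
CFL2,1
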