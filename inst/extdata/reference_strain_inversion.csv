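category,PF30,PF20,PF10,N0,DF10,DF20
CFL20,3.7,5.2,6.7,8.1,9.4,10.5
CFL30,-6.1,-3.7,-1.8,-0.5,0.3,0.4
CFL40,2.9,2.0,0.8,-0.5,-2.0,-3.6
CFL50,8.0,5.9,3.4,0.4,-2.8,-6.3
CFL2,14.1,13.2,12.5,11.8,11.2,10.8
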