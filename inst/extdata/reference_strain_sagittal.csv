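category,PF30,PF20,PF10,N0,DF10,DF20
CFL20,-4.5,-3.0,-1.4,0,1.3,2.4
CFL30,-6.4,-3.7,-1.6,0,1.0,1.5
CFL40,3.0,2.2,1.2,0,-1.4,-2.9
CFL50,7.0,5.1,2.7,0,-3.1,-6.5
CFL2,2.5,1.6,0.8,0,-0.7,-1.2
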