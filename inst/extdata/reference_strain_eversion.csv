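category,PF30,PF20,PF10,N0,DF10,DF20
CFL20,-10.1,-8.6,-7.0,-5.6,-4.2,-3.0
CFL30,5.0,-2.1,0.3,2.1,3.4,4.1
CFL40,6.5,5.8,5.0,3.8,2.5,1.0
CFL50,7.7,6.0,3.8,1.3,-1.7,-4.9
CFL2,-2.4,-3.3,-4.2,-5.1,-5.9,-6.5
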