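property,symbol,value,uncertainty,unit
thickness,e,0.12,0.02,mm
moisture_absorption,MA,3.9,0.2,%
water_solubility,WS,26.5,2.4,%
opacity,OP,1.1,0.1,A mm-1
water_vapor_permeability,WVP,1.8,0.3,g m-1 Pa-1 s-1
tensile_strength,TS,17.4,1.5,MPa
elongation_at_break,EB,122.7,5.1,%
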