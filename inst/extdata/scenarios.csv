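skull,scenario,L_out_mm
Euoplocephalus,muzzle,270.50
Euoplocephalus,anterior,201.90
Euoplocephalus,posterior,101.00
Panoplosaurus,muzzle,270.50
Panoplosaurus,anterior,201.90
Panoplosaurus,posterior,101.00
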