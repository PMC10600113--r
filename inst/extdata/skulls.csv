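skull,specimen,S_mm2
Euoplocephalus,AMNH 5405,867054
Panoplosaurus,ROM 1215,615095
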