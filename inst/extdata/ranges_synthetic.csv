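species,FAD_Ma,LAD_Ma
Scelidosaurus,196.5,189.0
Huayangosaurus,168.0,164.0
Stegouros,74.9,71.7
Kunbarrasaurus,102.0,99.6
Shamosaurus,125.0,113.0
Gobisaurus,122.0,112.0
Pinacosaurus,84.0,72.0
Saichania,75.0,71.0
Tarchia,75.0,69.0
Talarurus,96.0,89.0
Akainacephalus,76.0,74.0
Zuul,76.5,74.3
Euoplocephalus,76.5,75.5
Ankylosaurus,68.0,66.0
Sauropelta,115.0,108.0
Silvisaurus,100.0,93.0
Europelta,113.0,110.0
Struthiosaurus,85.0,66.0
Hungarosaurus,86.0,84.0
Borealopelta,112.0,110.0
Nodosaurus,100.0,95.0
Animantarx,99.0,93.0
Panoplosaurus,76.5,75.0
Edmontonia,76.5,69.0
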