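species,AMA,PMA
Scelidosaurus,0.13,0.45
Huayangosaurus,0.14,0.48
Stegouros,0.16,0.44
Kunbarrasaurus,0.20,0.38
Shamosaurus,0.14,0.33
Gobisaurus,0.17,0.40
Pinacosaurus,0.19,0.42
Saichania,0.20,0.43
Tarchia,0.27,0.47
Talarurus,0.19,0.41
Akainacephalus,0.28,0.49
Zuul,0.15,0.33
Euoplocephalus,0.16,0.34
Ankylosaurus,0.14,0.32
Sauropelta,0.27,0.52
Silvisaurus,0.17,0.51
Europelta,0.21,0.47
Struthiosaurus,0.20,0.46
Hungarosaurus,0.18,0.44
Borealopelta,0.22,0.50
Nodosaurus,0.21,0.49
Animantarx,0.26,0.56
Panoplosaurus,0.29,0.60
Edmontonia,0.28,0.58
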