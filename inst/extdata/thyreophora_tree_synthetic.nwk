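(Scelidosaurus,(Huayangosaurus,((Stegouros,Kunbarrasaurus),((Shamosaurus,(Gobisaurus,((Pinacosaurus,(Saichania,Tarchia)),(Talarurus,(Akainacephalus,(Zuul,(Euoplocephalus,Ankylosaurus))))))),(Sauropelta,((Silvisaurus,(Europelta,(Struthiosaurus,Hungarosaurus))),(Borealopelta,(Nodosaurus,(Animantarx,(Panoplosaurus,Edmontonia))))))))));
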