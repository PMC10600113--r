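skull,muscle,ML_mm,MV_mm3
Euoplocephalus,mAMEP,196.6,47100.0
Euoplocephalus,mAMEM,179.8,46500.0
Euoplocephalus,mAMES,189.1,64500.0
Euoplocephalus,mPTd,127.8,36600.0
Euoplocephalus,mPTv,173.8,115000.0
Euoplocephalus,mAMP,148.5,24800.0
Euoplocephalus,mPSTs,225.0,30400.0
Panoplosaurus,mAMEP,186.7,25500.0
Panoplosaurus,mAMEM,154.5,45000.0
Panoplosaurus,mAMES,137.7,21900.0
Panoplosaurus,mPTd,110.9,16600.0
Panoplosaurus,mPTv,133.8,75400.0
Panoplosaurus,mAMP,126.6,24600.0
Panoplosaurus,mPSTs,197.8,18400.0
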