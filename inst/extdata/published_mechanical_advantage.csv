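skull,muscle,MA_muz,MA_ante,MA_post
Euoplocephalus,mAMEP,0.20,0.27,0.55
Euoplocephalus,mAMEM,0.16,0.21,0.42
Euoplocephalus,mAMES,0.18,0.24,0.47
Euoplocephalus,mPTd,0.02,0.03,0.05
Euoplocephalus,mPTv,0.05,0.07,0.14
Euoplocephalus,mAMP,0.12,0.16,0.31
Euoplocephalus,mPSTs,0.19,0.25,0.50
Panoplosaurus,mAMEP,0.29,0.42,0.69
Panoplosaurus,mAMEM,0.21,0.28,0.46
Panoplosaurus,mAMES,0.19,0.25,0.42
Panoplosaurus,mPTd,0.03,0.04,0.06
Panoplosaurus,mPTv,0.05,0.07,0.12
Panoplosaurus,mAMP,0.14,0.19,0.30
Panoplosaurus,mPSTs,0.21,0.28,0.46
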