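skull,muscle,ML_mm,FL_mm,MV_mm3,PCSA_mm2,F_mus_N,F_scaled_N,RMF_pct
Euoplocephalus,mAMEP,196.6,65.5,47100.0,719.0,215.7,NA,11.5
Euoplocephalus,mAMEM,179.8,59.9,46500.0,775.4,232.6,NA,12.4
Euoplocephalus,mAMES,189.1,63.0,64500.0,1024.3,307.3,NA,16.3
Euoplocephalus,mPTd,127.8,42.6,36600.0,859.5,257.9,NA,13.7
Euoplocephalus,mPTv,173.8,57.9,115000.0,1992.7,597.8,NA,31.7
Euoplocephalus,mAMP,148.5,49.5,24800.0,501.3,150.4,NA,8.0
Euoplocephalus,mPSTs,225.0,75.0,30400.0,405.3,121.6,NA,6.5
Panoplosaurus,mAMEP,186.7,62.2,25500.0,410.0,122.9,173.2,8.6
Panoplosaurus,mAMEM,154.5,51.5,45000.0,874.0,262.2,368.5,18.3
Panoplosaurus,mAMES,137.7,45.9,21900.0,477.0,143.1,201.4,10.0
Panoplosaurus,mPTd,110.9,37.0,16600.0,449.0,134.7,189.3,9.4
Panoplosaurus,mPTv,133.8,44.6,75400.0,1690.0,507.2,714.9,35.5
Panoplosaurus,mAMP,126.6,42.2,24600.0,583.0,174.9,245.7,12.2
Panoplosaurus,mPSTs,197.8,65.9,18400.0,279.0,83.7,118.8,5.9
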