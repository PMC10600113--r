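skull,muscle,alpha_deg,beta_deg,d_mm,q_deg,L_in_mm
Euoplocephalus,mAMEP,38.00,14.00,59.60,68.10,55.30
Euoplocephalus,mAMEM,36.00,5.30,42.70,87.30,42.65
Euoplocephalus,mAMES,38.00,9.70,47.70,86.60,47.62
Euoplocephalus,mPTd,34.00,37.00,17.60,17.80,5.38
Euoplocephalus,mPTv,15.00,42.00,26.20,33.50,14.46
Euoplocephalus,mAMP,36.00,5.00,49.10,35.50,31.40
Euoplocephalus,mPSTs,20.00,20.00,81.20,38.20,50.40
Panoplosaurus,mAMEP,47.00,29.50,82.50,75.50,79.87
Panoplosaurus,mAMEM,45.00,22.00,61.00,86.70,60.90
Panoplosaurus,mAMES,49.00,21.00,56.70,78.20,55.50
Panoplosaurus,mPTd,49.00,21.00,13.80,35.20,7.95
Panoplosaurus,mPTv,11.00,20.00,21.10,43.30,14.47
Panoplosaurus,mAMP,51.00,26.00,60.70,58.30,43.80
Panoplosaurus,mPSTs,41.00,33.00,90.20,56.40,69.60
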