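skull,panel,muscle,F_res_N,F_muz_N,F_ante_N,F_post_N
Euoplocephalus,original,mAMEP,172.55,33.71,45.17,90.29
Euoplocephalus,original,mAMEM,188.56,29.55,39.59,79.13
Euoplocephalus,original,mAMES,243.92,42.01,56.29,112.52
Euoplocephalus,original,mPTd,229.43,3.40,4.55,9.09
Euoplocephalus,original,mPTv,586.54,22.94,30.74,61.44
Euoplocephalus,original,mAMP,121.87,14.07,18.85,37.68
Euoplocephalus,original,mPSTs,115.12,20.01,26.80,53.58
Panoplosaurus,original,mAMEP,72.97,21.28,30.42,49.99
Panoplosaurus,original,mAMEM,195.67,43.50,54.63,89.77
Panoplosaurus,original,mAMES,99.86,20.24,25.39,41.72
Panoplosaurus,original,mPTd,93.99,2.73,3.43,5.63
Panoplosaurus,original,mPTv,498.92,26.36,35.33,58.06
Panoplosaurus,original,mAMP,121.86,19.49,22.62,37.17
Panoplosaurus,original,mPSTs,69.10,17.56,19.25,31.63
Panoplosaurus,scaled,mAMEP,102.81,29.98,42.86,70.42
Panoplosaurus,scaled,mAMEM,275.04,61.15,76.79,126.18
Panoplosaurus,scaled,mAMES,140.55,28.48,35.73,58.72
Panoplosaurus,scaled,mPTd,132.10,3.84,4.81,7.91
Panoplosaurus,scaled,mPTv,703.30,37.16,49.81,81.84
Panoplosaurus,scaled,mAMP,171.18,27.37,31.77,52.21
Panoplosaurus,scaled,mPSTs,98.04,24.91,27.32,44.88
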