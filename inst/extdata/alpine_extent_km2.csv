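species,current,GFDL-ESM4,IPSL-CM6A-LR,MRI-ESM2-0,UKESM1-0-LL,refugia1,refugia2,refugia3
rock ptarmigan,38024,28721,24705,28867,15455,13170,1514,1807
water pipit,42776,45565,44183,46077,38795,29796,5882,6672
alpine accentor,40054,33318,29636,32576,22798,20874,1093,1362
snowfinch,29783,24410,23181,24200,18157,15837,1247,1642
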