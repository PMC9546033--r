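species,current,IPSL-CM6A-LR,GFDL-ESM4,MRI-ESM2-0,UKESM1-0-LL
rock ptarmigan,2187,2493,2433,2424,2644
water pipit,1924,2220,2180,2161,2335
alpine accentor,2214,2466,2416,2416,2584
snowfinch,2301,2538,2507,2491,2653
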