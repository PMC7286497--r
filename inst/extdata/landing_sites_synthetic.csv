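site_id,lat,lon
LS1,0.392,9.452
LS2,0.463,9.414
LS3,0.571,9.368
LS4,0.618,9.321
LS5,0.989,9.331
LS6,1.083,9.292
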