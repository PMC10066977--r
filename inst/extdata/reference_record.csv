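fio2,hb,sao2,ph,pao2,paco2,mean_paco2,co,vco2,r
0.38,9.30,0.94,7.364,69.0,39.4,30.1,5.25,187,0.74
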