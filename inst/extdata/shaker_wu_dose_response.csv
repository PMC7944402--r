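compound,channel,ec50_uM,ec50_sem_uM,dvmax_mV,dvmax_sem_mV,pH
Wu50,WT,29.1,3.5,-36.1,1.3,9.0
Wu50,2R,30.0,5.0,-56.5,2.6,9.0
Wu50,2R/W454A,27.9,9.2,-62.3,6.5,9.0
Wu161,WT,43.7,6.3,-13.9,0.6,7.4
Wu161,2R,36.4,9.0,-45.5,3.5,7.4
Wu181,WT,1.6,0.6,-7.8,0.5,7.4
Wu181,2R,6.1,1.7,-53.6,4.0,7.4
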