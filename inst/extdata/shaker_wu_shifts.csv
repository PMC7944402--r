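compound,mutant_label,has_2R,R362Q,R365Q,W454A,F416A,concentration_uM,pH,shift_mV,sem_mV,n,status,derived,model_panel,source
Wu50,WT,FALSE,FALSE,FALSE,FALSE,FALSE,100,9.0,-25.5,1.4,5,ok,FALSE,TRUE,results_text
Wu50,2R,TRUE,FALSE,FALSE,FALSE,FALSE,100,9.0,-40.0,2.7,8,ok,FALSE,TRUE,results_text
Wu50,R362Q,FALSE,TRUE,FALSE,FALSE,FALSE,100,9.0,-49.6,1.2,3,ok,FALSE,TRUE,results_text
Wu50,W454A,FALSE,FALSE,FALSE,TRUE,FALSE,100,9.0,-8.1,0.4,5,ok,FALSE,TRUE,results_text
Wu50,R362Q/W454A,FALSE,TRUE,FALSE,TRUE,FALSE,100,9.0,-41.0,4.4,5,ok,FALSE,TRUE,results_text
Wu50,2R/R362Q,TRUE,TRUE,FALSE,FALSE,FALSE,100,9.0,-54.0,2.3,4,ok,FALSE,TRUE,results_text
Wu50,2R/W454A,TRUE,FALSE,FALSE,TRUE,FALSE,100,9.0,-40.1,NA,3,ok,TRUE,TRUE,derived_range
Wu50,2R/R362Q/W454A,TRUE,TRUE,FALSE,TRUE,FALSE,100,9.0,-56.6,5.8,4,ok,FALSE,TRUE,results_text
Wu50,R362Q/R365Q,FALSE,TRUE,TRUE,FALSE,FALSE,100,9.0,-25.5,4.6,5,ok,FALSE,FALSE,results_text
Wu50,R362Q/R365Q/W454A,FALSE,TRUE,TRUE,TRUE,FALSE,100,9.0,-24.7,3.0,6,ok,FALSE,FALSE,results_text
Wu50,R362Q/W454A/F416A,FALSE,TRUE,FALSE,TRUE,TRUE,100,9.0,NA,NA,NA,gmax_block,FALSE,FALSE,results_text
Wu161,WT,FALSE,FALSE,FALSE,FALSE,FALSE,100,7.4,-9.8,1.1,5,ok,FALSE,TRUE,results_text
Wu161,2R,TRUE,FALSE,FALSE,FALSE,FALSE,100,7.4,-32.0,2.7,6,ok,FALSE,TRUE,results_text
Wu161,R362Q,FALSE,TRUE,FALSE,FALSE,FALSE,100,7.4,-8.5,0.5,3,ok,FALSE,TRUE,results_text
Wu161,W454A,FALSE,FALSE,FALSE,TRUE,FALSE,100,7.4,-5.6,0.8,4,ok,FALSE,TRUE,results_text
Wu161,R362Q/R365Q,FALSE,TRUE,TRUE,FALSE,FALSE,100,7.4,-5.2,1.2,4,ok,FALSE,TRUE,results_text
Wu161,R362Q/F416A/W454A,FALSE,TRUE,FALSE,TRUE,TRUE,100,7.4,NA,NA,NA,shift_eliminated,FALSE,FALSE,results_text
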