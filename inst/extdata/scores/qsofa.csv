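channel,criterion,lower,lower_open,upper,points
respiratory_rate,respiratory_rate,-Inf,FALSE,22,0
respiratory_rate,respiratory_rate,22,FALSE,Inf,1
systolic_bp,systolic_bp,-Inf,FALSE,100,1
systolic_bp,systolic_bp,100,TRUE,Inf,0
consciousness,consciousness,-Inf,FALSE,1,0
consciousness,consciousness,1,FALSE,Inf,1
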