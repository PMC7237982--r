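channel,criterion,lower,lower_open,upper,points
respiratory_rate,respiratory_rate,-Inf,FALSE,5,1
respiratory_rate,respiratory_rate,5,FALSE,30,0
respiratory_rate,respiratory_rate,30,TRUE,Inf,1
spo2,spo2,-Inf,FALSE,90,1
spo2,spo2,90,FALSE,Inf,0
heart_rate,heart_rate,-Inf,FALSE,40,1
heart_rate,heart_rate,40,FALSE,140,0
heart_rate,heart_rate,140,TRUE,Inf,1
systolic_bp,systolic_bp,-Inf,FALSE,90,1
systolic_bp,systolic_bp,90,FALSE,Inf,0
consciousness,consciousness,-Inf,FALSE,2,0
consciousness,consciousness,2,FALSE,Inf,1
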