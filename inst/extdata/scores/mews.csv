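channel,criterion,lower,lower_open,upper,points
systolic_bp,systolic_bp,-Inf,FALSE,71,3
systolic_bp,systolic_bp,71,FALSE,81,2
systolic_bp,systolic_bp,81,FALSE,101,1
systolic_bp,systolic_bp,101,FALSE,200,0
systolic_bp,systolic_bp,200,FALSE,Inf,2
heart_rate,heart_rate,-Inf,FALSE,41,2
heart_rate,heart_rate,41,FALSE,51,1
heart_rate,heart_rate,51,FALSE,101,0
heart_rate,heart_rate,101,FALSE,111,1
heart_rate,heart_rate,111,FALSE,130,2
heart_rate,heart_rate,130,FALSE,Inf,3
respiratory_rate,respiratory_rate,-Inf,FALSE,9,2
respiratory_rate,respiratory_rate,9,FALSE,15,0
respiratory_rate,respiratory_rate,15,FALSE,21,1
respiratory_rate,respiratory_rate,21,FALSE,30,2
respiratory_rate,respiratory_rate,30,FALSE,Inf,3
temperature,temperature,-Inf,FALSE,35,2
temperature,temperature,35,FALSE,38.5,0
temperature,temperature,38.5,FALSE,Inf,2
consciousness,consciousness,-Inf,FALSE,1,0
consciousness,consciousness,1,FALSE,2,1
consciousness,consciousness,2,FALSE,3,2
consciousness,consciousness,3,FALSE,Inf,3
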