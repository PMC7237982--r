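channel,criterion,lower,lower_open,upper,points
respiratory_rate,respiratory_rate,-Inf,FALSE,9,3
respiratory_rate,respiratory_rate,9,FALSE,12,1
respiratory_rate,respiratory_rate,12,FALSE,21,0
respiratory_rate,respiratory_rate,21,FALSE,25,2
respiratory_rate,respiratory_rate,25,FALSE,Inf,3
spo2,spo2,-Inf,FALSE,92,3
spo2,spo2,92,FALSE,94,2
spo2,spo2,94,FALSE,96,1
spo2,spo2,96,FALSE,Inf,0
supplemental_o2,supplemental_o2,-Inf,FALSE,1,0
supplemental_o2,supplemental_o2,1,FALSE,Inf,2
temperature,temperature,-Inf,FALSE,35.1,3
temperature,temperature,35.1,FALSE,36.1,1
temperature,temperature,36.1,FALSE,38.1,0
temperature,temperature,38.1,FALSE,39.1,1
temperature,temperature,39.1,FALSE,Inf,2
systolic_bp,systolic_bp,-Inf,FALSE,91,3
systolic_bp,systolic_bp,91,FALSE,101,2
systolic_bp,systolic_bp,101,FALSE,111,1
systolic_bp,systolic_bp,111,FALSE,220,0
systolic_bp,systolic_bp,220,FALSE,Inf,3
heart_rate,heart_rate,-Inf,FALSE,41,3
heart_rate,heart_rate,41,FALSE,51,1
heart_rate,heart_rate,51,FALSE,91,0
heart_rate,heart_rate,91,FALSE,111,1
heart_rate,heart_rate,111,FALSE,131,2
heart_rate,heart_rate,131,FALSE,Inf,3
consciousness,consciousness,-Inf,FALSE,1,0
consciousness,consciousness,1,FALSE,Inf,3
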