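channel,criterion,lower,lower_open,upper,points
temperature,temperature,-Inf,FALSE,36,1
temperature,temperature,36,FALSE,38,0
temperature,temperature,38,TRUE,Inf,1
heart_rate,heart_rate,-Inf,FALSE,90,0
heart_rate,heart_rate,90,TRUE,Inf,1
respiratory_rate,resp_or_paco2,-Inf,FALSE,20,0
respiratory_rate,resp_or_paco2,20,TRUE,Inf,1
paco2,resp_or_paco2,-Inf,FALSE,32,1
paco2,resp_or_paco2,32,FALSE,Inf,0
wbc,wbc_or_bands,-Inf,FALSE,4,1
wbc,wbc_or_bands,4,FALSE,12,0
wbc,wbc_or_bands,12,TRUE,Inf,1
band_fraction,wbc_or_bands,-Inf,FALSE,10,0
band_fraction,wbc_or_bands,10,TRUE,Inf,1
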