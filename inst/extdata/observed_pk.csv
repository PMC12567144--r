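api,metric,observed
RIF,cmax,5.81
RIF,auc_0_t,31.02
RIF,auc_0_inf,31.02
ETH,cmax,3.54
ETH,auc_0_t,27.8
ETH,auc_0_inf,30.76
MOX,cmax,1.16
MOX,auc_0_t,11.88
MOX,auc_0_inf,14.57
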