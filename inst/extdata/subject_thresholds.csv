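subject,emg_threshold_mA,ecap_threshold_mA
S1,2,1.2
S2,2.4,1.6
S3,1.8,0.9
S4,2.4,2
S5,3,2.1
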