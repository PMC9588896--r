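dose_mg,n_patients,n_dlt_patients
40,3,0
120,2,0
360,2,0
720,17,0
1000,5,1
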