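dose_mg,n_patients,n_dlt_patients
40,2,0
120,5,1
150,3,0
180,11,1
240,3,2
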