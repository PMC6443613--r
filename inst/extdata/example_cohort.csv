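patient_id,vessel_id,ccta_grade,ffr,ica_ds_percent,prior_event,true_label
P001,1,G2,0.8897,48.7,TRUE,FALSE
P002,1,G3,0.8789,61.6,FALSE,FALSE
P003,1,G1,0.8798,6.4,FALSE,FALSE
P003,2,G0,0.8845,2,FALSE,FALSE
P004,1,G4,0.7437,82.8,FALSE,TRUE
P004,2,G2,0.9038,48.5,FALSE,TRUE
P005,1,G3,0.7168,53.9,FALSE,TRUE
P005,2,G0,0.8633,3,FALSE,TRUE
P005,3,G2,0.8629,35.9,FALSE,TRUE
P006,1,G3,0.5996,65.1,FALSE,TRUE
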