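patient_id,label,psa,gleason
P0001,higher_risk,11.42,<=6
P0002,higher_risk,25.77,3+4
P0003,higher_risk,11.88,9-10
P0004,lower_risk,6.05,4+3
P0005,lower_risk,34.57,3+4
P0006,lower_risk,105.42,3+4
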