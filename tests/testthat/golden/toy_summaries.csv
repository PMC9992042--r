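operation,value
TI_ba_patient1,3
Max_pb_patient4,4
Avg_pb_patient2,2
TI_ba_patient3,0
TI_pb_patient6,3.5
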