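tissue	sample_id
kidney	GSM252083
kidney	GSM252084
kidney	GSM252085
liver	GSM252074
liver	GSM252075
liver	GSM252076
lung	GSM252080
lung	GSM252081
lung	GSM252082
heart	GSM252113
heart	GSM252114
heart	GSM252115
muscle	GSM252070
muscle	GSM252071
muscle	GSM252072
muscle	GSM252073
adipose	GSM252093
adipose	GSM252094
adipose	GSM252095
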