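tissue	sample_id
kidney	GSM18955
kidney	GSM18956
liver	GSM18953
liver	GSM18954
lung	GSM18949
lung	GSM18950
heart	GSM18951
heart	GSM18952
muscle	GSM19013
muscle	GSM19014
adipose	GSM18975
adipose	GSM18976
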