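surrogate,group,rate_label,rate_mm_per_s,c1_MPa,c2_MPa,c3_MPa
60-20-10-10,healthy control,1.96 mm/s,1.96,0.0002,0.0090,0.0080
60-20-10-10,healthy control,180 mm/s,180,0.0050,0.0100,0.0120
60-20-10-10,healthy control,1800 mm/s,1800,0.7200,0.3500,0.8800
55-20-15-10,plantar pain,1.96 mm/s,1.96,0.0004,0.0090,0.0100
45-20-20-15,diabetes,1.96 mm/min,1.96,0.0006,0.0150,0.0100
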