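estuary,SY_m3_yr,TP_m3,amsl
synthetic_barrier_A,30000,9.0e6,0.55
synthetic_barrier_B,12000,1.1e7,0.32
synthetic_barrier_C,60000,8.0e6,0.71
synthetic_headland_D,8000,2.5e7,0.12
synthetic_headland_E,20000,1.8e7,0.28
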