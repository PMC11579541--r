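route,t_start_h,t_end_h,interval_pct,cumulative_pct
feces,0,5,0.010,0.010
feces,5,12,0.206,0.216
feces,12,24,0.145,0.361
feces,24,48,0.019,0.380
feces,48,72,0.002,0.382
urine,0,5,0.116,0.116
urine,5,12,0.107,0.223
urine,12,24,0.050,0.273
urine,24,48,0.014,0.287
urine,48,72,0.005,0.292
bile,0,5,0.089,0.089
bile,5,12,0.182,0.271
bile,12,24,0.149,0.420
bile,24,48,0.000,0.420
bile,48,72,0.016,0.436
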