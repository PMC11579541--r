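species,t_half_min,t_half_sd,cl_int,cl_int_sd,cl_h,cl_h_sd
human,249.30,6.09,16.08,0.40,9.05,0.13
dog,138.42,2.96,36.07,0.78,16.64,0.17
monkey,7.57,0.12,618.10,9.67,40.73,0.04
rat,12.81,0.99,489.11,38.21,49.58,0.39
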