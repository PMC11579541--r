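species,dose_mg_per_kg,auc_0t,cmax
rat,8,1366.14,287.19
rat,20,3200.20,399.75
rat,50,11011.21,987.12
dog,2,417.73,165.18
dog,5,1955.33,523.70
dog,12.5,7899.46,1472.40
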