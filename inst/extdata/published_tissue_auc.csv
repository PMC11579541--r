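matrix,auc_0t,ratio_to_blood
blood,2615.20,NA
heart,44743.11,17.11
liver,208081.20,81.37
spleen,117673.30,46.03
lung,393670.80,154.85
kidney,98000.01,37.66
brain,60541.26,23.26
intestine,190710.5,75.61
stomach,118279.40,48.76
fat,38592.32,14.15
muscle,24154.50,9.31
testis,69347.84,27.32
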