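organ,external_mSv,internal_mSv,total_mSv
anterior_rectal_wall,228,561,788
bladder,222,363,585
ctv,228,840,1067
distal_seminal_vesicles,233,691,924
femoral_heads,280,531,811
prostate,227,841,1068
proximal_seminal_vesicles,239,814,1053
rectum,223,425,648
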