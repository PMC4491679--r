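organ,external_mSv,internal_mSv,total_mSv
anterior_rectal_wall,174,641,815
bladder,170,413,582
ctv,172,938,1110
distal_seminal_vesicles,173,787,960
femoral_heads,217,572,789
prostate,173,941,1113
proximal_seminal_vesicles,169,873,1042
rectum,171,481,652
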