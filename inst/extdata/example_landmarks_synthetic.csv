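name,x,y
chelion_l,83.2,168.96
mid_chelion_l_1,97.8761902,159.821731875
mid_chelion_l_2,108.83063942963,154.462771365741
bow_peak_l,117.71922962963,152.600740740741
mid_bow_peak_l_1,123.157037037037,153.731759259259
labiale_superius,128,157.06
mid_labiale_superius_1,132.842962962963,153.731759259259
bow_peak_r,138.28077037037,152.600740740741
mid_bow_peak_r_1,152.30482962963,156.712592592593
chelion_r,172.8,168.96
mid_chelion_r_1,151.87,170.61375
stomion,128,171.165
mid_stomion_1,104.13,170.61375
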