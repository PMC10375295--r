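variety,plant_id,true_count,correct_count
Huayouza 62,1,126,124
Huayouza 62,2,196,192
Huayouza 62,3,110,108
Huayouza 62,4,119,117
Zhongshuang 6,5,104,102
Zhongshuang 6,6,139,135
Zhongshuang 6,7,85,83
Zhongshuang 6,8,99,98
Dadi 55,9,129,126
Dadi 55,10,105,104
Dadi 55,11,124,121
Dadi 55,12,118,115
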