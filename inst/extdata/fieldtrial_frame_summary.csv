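table,image,feature,nobird_fp_frames,pct_nobird_fp,bird_tp_frames,pct_bird_tp
table1B,full,haar,8927,81,1116,61
table1B,full,lbp,6408,58,936,51
table2B,full,haar,8314,75,358,49
table2B,full,lbp,6682,60,253,34
table1B,cropped,haar,8835,79,1093,60
table1B,cropped,lbp,5316,48,915,50
table2B,cropped,haar,8222,74,335,46
table2B,cropped,lbp,5193,47,241,33
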