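table,image,feature,precision,recall,f_measure,fnr,far
table1B,full,haar,0.010,0.542,0.020,0.552,0.989
table1B,full,lbp,0.045,0.457,0.083,0.545,0.954
table2B,full,haar,0.003,0.411,0.006,0.603,0.997
table2B,full,lbp,0.012,0.290,0.023,0.711,0.987
table1B,cropped,haar,0.016,0.531,0.031,0.563,0.984
table1B,cropped,lbp,0.068,0.448,0.119,0.492,0.931
table2B,cropped,haar,0.007,0.388,0.013,0.624,0.993
table2B,cropped,lbp,0.022,0.276,0.040,0.717,0.978
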