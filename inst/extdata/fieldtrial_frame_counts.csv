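table,total_frames,frames_with_birds,frames_without_birds
table1B,11067,1825,9242
table2B,11067,730,10337
Total,22134,2555,19579
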