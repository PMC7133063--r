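name,n_fast,n_slow,pixel_size,module_fast,module_slow,gap_fast,gap_slow
pilatus6m,2463,2527,172e-6,487,195,7,17
pilatus2m,1475,1679,172e-6,487,195,7,17
pilatus1m,981,1043,172e-6,487,195,7,17
eiger16m,4150,4371,75e-6,1030,514,10,37
eiger9m,3110,3269,75e-6,1030,514,10,37
eiger4m,2070,2167,75e-6,1030,514,10,37
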