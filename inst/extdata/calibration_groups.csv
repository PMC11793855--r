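group,n_subjects,quantity,mean,sd,provenance
I,24,hbt_index_i,0.6795,0.0278,reported
I,24,hbt_index_ii,0.6409,0.0289,reported
I,24,hbt_index_iii,0.6680,0.0300,reported
I,24,hbt_index_vi,0.8399,0.3756,reported
I,24,sto2_index_ii,52.35,0.90,assumed
I,24,sto2_index_vii,9.2185,12.0192,reported
II,14,hbt_index_i,0.6770,0.0285,assumed
II,14,hbt_index_ii,0.6361,0.0315,reported
II,14,hbt_index_iii,0.6695,0.0276,reported
II,14,hbt_index_vi,0.8700,0.3800,assumed
II,14,sto2_index_ii,52.4154,0.9043,reported
II,14,sto2_index_vii,8.0000,11.0000,assumed
III,51,hbt_index_i,0.6546,0.0275,reported
III,51,hbt_index_ii,0.6108,0.0293,reported
III,51,hbt_index_iii,0.6475,0.0295,reported
III,51,hbt_index_vi,1.1222,0.6491,reported
III,51,sto2_index_ii,51.75,0.87,assumed
III,51,sto2_index_vii,2.9323,9.5071,reported
IV,13,hbt_index_i,0.6454,0.0456,reported
IV,13,hbt_index_ii,0.6060,0.0455,reported
IV,13,hbt_index_iii,0.6416,0.0455,reported
IV,13,hbt_index_vi,1.2393,0.4759,reported
IV,13,sto2_index_ii,51.5932,0.8693,reported
IV,13,sto2_index_vii,2.8658,10.8890,reported
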