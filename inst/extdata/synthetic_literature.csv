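miRNA,n_up,n_down
hsa-mir-21,12,0
hsa-mir-148a,0,8
hsa-mir-100,0,6
hsa-mir-30a,0,5
hsa-let-7g,0,4
hsa-mir-221,6,0
hsa-mir-222,5,0
hsa-mir-1246,4,2
hsa-mir-492,1,1
hsa-mir-612,1,0
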