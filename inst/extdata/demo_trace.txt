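12.140
11.732
11.908
11.999
12.296
12.252
12.212
12.392
11.584
12.382
12.055
12.226
12.178
11.705
11.917
 3.739
 4.216
 4.033
 3.976
 3.874
 3.831
 4.299
 3.668
 3.957
 4.094
 4.366
 3.790
 3.914
 3.607
 3.883
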