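# size-class sighted counts (M) and pooled Lincoln-Petersen population estimates (N)
size_class,time_of_day,m,n_hat
VS,day,9,18
VS,night,16,36
S,day,140,188
S,night,179,203
M,day,74,98
M,night,95,105
L,day,26,33
L,night,32,34
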