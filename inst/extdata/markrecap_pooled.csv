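# pooled mark-recapture sighting totals against the pooled max-N estimate (12 transects, 4500 m2)
time_of_day,n_sighted,n_hat
day,266,411
night,322,411
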