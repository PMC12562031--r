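# pooled three-pass removal series across 40 transects of 200 m2 (8000 m2 total)
transect_id,site,zone,aspect,area_m2,survey_index,time_of_day,n_sighted,n_newly_marked,n_recaptured,n_removed
pooled_all,pooled,crest,windward,8000,1,day,96,0,0,96
pooled_all,pooled,crest,windward,8000,2,day,25,0,0,25
pooled_all,pooled,crest,windward,8000,3,day,11,0,0,11
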