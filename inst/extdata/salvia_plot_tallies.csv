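plot,focal_species,cross_bouts,total_bouts,het_transitions,total_transitions
plot1,flava,4,52,5,70
plot2,castanea,8,129,9,203
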