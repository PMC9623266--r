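species,start_date,end_date
flava,2019-07-20,2019-09-25
castanea,2019-08-01,2019-10-15
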