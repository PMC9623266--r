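species,pollinator_taxon,visits
flava,honeybee,169
flava,bumblebee,7
castanea,honeybee,194
castanea,bumblebee,21
castanea,anthophora,3
castanea,eristalis,1
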