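stage,stage_class,flava,castanea,allopatric_only
Geographic,prezygotic,0.81,0.88,TRUE
Phenology,prezygotic,0.13,0.26,FALSE
Pollinator assemblage,prezygotic,0,0.0183,FALSE
Pollinator ethological,prezygotic,0.9945,0.9973,FALSE
Fruit set,postzygotic,0,0.0244,FALSE
Seed production,postzygotic,0.0649,0.0350,FALSE
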