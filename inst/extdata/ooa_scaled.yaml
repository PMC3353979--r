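# Scaled three-population Out-of-Africa timeline (N0 = 500 diploids).
# Times in units of 2*N0 generations, forward from simulation start.
# Migration payloads are migrant gene copies per generation into 'pop'
# from 'pop2' (2*N*m; the underlying per-generation fractions are
# symmetric between each population pair).
N0: 500
t_end: 0.607
generation_time_years: 25.0
kappa: 14.62
migration_convention: copies
populations:
- AFR
- EUR
- ASN
record_times:
  7kYBP: 0.5895
events:
- {time: 0.0,      kind: size_change,        pop: AFR, value: 0.1}
- {time: 0.004,    kind: size_change,        pop: AFR, value: 10.0}
- {time: 0.005,    kind: size_change,        pop: AFR, value: 1.68202}
- {time: 0.211074, kind: split,              pop: AFR, pop2: EUR}
- {time: 0.211074, kind: size_change,        pop: EUR, value: 0.170737565}
- {time: 0.211074, kind: migration_change,   pop: AFR, pop2: EUR, value: 6.133603671}
- {time: 0.211074, kind: migration_change,   pop: EUR, pop2: AFR, value: 1.047236559}
- {time: 0.534772, kind: split,              pop: EUR, pop2: ASN}
- {time: 0.534772, kind: size_change,        pop: EUR, value: 0.724763218}
- {time: 0.534772, kind: size_change,        pop: ASN, value: 0.162342748}
- {time: 0.534772, kind: growth_rate_change, pop: EUR, value: 33.98}
- {time: 0.534772, kind: growth_rate_change, pop: ASN, value: 62.27}
- {time: 0.534772, kind: migration_change,   pop: AFR, pop2: EUR, value: 0.741012229}
- {time: 0.534772, kind: migration_change,   pop: AFR, pop2: ASN, value: 0.472619025}
- {time: 0.534772, kind: migration_change,   pop: EUR, pop2: AFR, value: 0.091696045}
- {time: 0.534772, kind: migration_change,   pop: EUR, pop2: ASN, value: 0.41215962}
- {time: 0.534772, kind: migration_change,   pop: ASN, pop2: AFR, value: 0.013100056}
- {time: 0.534772, kind: migration_change,   pop: ASN, pop2: EUR, value: 0.092321359}
- {time: 0.54805,  kind: migration_change,   pop: AFR, pop2: EUR, value: 0.0}
- {time: 0.54805,  kind: migration_change,   pop: AFR, pop2: ASN, value: 0.0}
- {time: 0.54805,  kind: migration_change,   pop: EUR, pop2: AFR, value: 0.0}
- {time: 0.54805,  kind: migration_change,   pop: ASN, pop2: AFR, value: 0.0}
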