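# Published-summary fixture: printed flowering dates, transition counts
# and crossing summary statistics encoded as ordinary pipeline inputs.
# The fruit-production rows carry conspecific success normalised to 1
# and heterospecific success inverted from the published RI via
# h = (1 - RI) / (1 + RI) (no raw fruit-set rates were published).
flowering: flowering.csv
transitions: transitions.csv
barriers: barriers.csv
forms: [white, pink]
barrier_order: [pollinator, pollen_tube, fruit, seed]
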