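barrier,maternal_form,conspecific,heterospecific,n
pollen_tube,white,118.93,125.62,30
pollen_tube,pink,83.95,69.75,19
fruit,white,1,0.4388489208633094,30
fruit,pink,1,0.8867924528301887,30
seed,white,72.42,45.51,33
seed,pink,65.48,63.35,29
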