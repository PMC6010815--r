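"wavelength_nm","green_foliage"
300,0.04
305,0.04
310,0.04
315,0.04
320,0.04
325,0.04
330,0.04
335,0.04
340,0.04
345,0.04
350,0.04
355,0.04
360,0.04
365,0.04
370,0.04
375,0.04
380,0.04
385,0.04
390,0.04
395,0.04
400,0.04
405,0.04
410,0.04
415,0.04
420,0.04
425,0.04
430,0.04001
435,0.04002
440,0.04004
445,0.04008
450,0.04015
455,0.04028
460,0.0405
465,0.04088
470,0.0415
475,0.04246
480,0.04392
485,0.04605
490,0.04905
495,0.05313
500,0.05845
505,0.06514
510,0.0732
515,0.0825
520,0.09273
525,0.10341
530,0.1139
535,0.12347
540,0.13139
545,0.13698
550,0.13975
555,0.13944
560,0.13608
565,0.12998
570,0.12167
575,0.11185
580,0.10126
585,0.09063
590,0.08056
595,0.07149
600,0.06369
605,0.05728
610,0.05222
615,0.04837
620,0.04556
625,0.04359
630,0.04225
635,0.04139
640,0.04086
645,0.04059
650,0.04051
655,0.04061
660,0.04097
665,0.04171
670,0.04312
675,0.04575
680,0.05053
685,0.05897
690,0.07324
695,0.09568
700,0.12716
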