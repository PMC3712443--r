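wavelength_nm,value
300,0.04
310,0.04
320,0.04
330,0.04
340,0.04
350,0.04
360,0.04
370,0.04
380,0.04
390,0.04
400,0.04001
410,0.04004
420,0.04012
430,0.04032
440,0.04079
450,0.04183
460,0.04392
470,0.04773
480,0.05409
490,0.06369
500,0.07679
510,0.09273
520,0.10977
530,0.12521
540,0.13608
550,0.14
560,0.13608
570,0.12522
580,0.10977
590,0.09274
600,0.07681
610,0.06373
620,0.05418
630,0.04794
640,0.0444
650,0.04294
660,0.04332
670,0.04606
680,0.05295
690,0.06772
700,0.09569
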