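wavelength_nm,power
400,100
410,100
420,100
430,100
440,100
450,100
460,100
470,100
480,100
490,100
500,100
510,100
520,100
530,100
540,100
550,100
560,100
570,100
580,100
590,100
600,100
610,100
620,100
630,100
640,100
650,100
660,100
670,100
680,100
690,100
700,100
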