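wavelength_nm,value,units
400,266232,L.mol-1.cm-1
410,466840,L.mol-1.cm-1
420,480360,L.mol-1.cm-1
430,246072,L.mol-1.cm-1
440,102580,L.mol-1.cm-1
450,62816,L.mol-1.cm-1
460,44480,L.mol-1.cm-1
470,33209.2,L.mol-1.cm-1
480,26629.2,L.mol-1.cm-1
490,23684.4,L.mol-1.cm-1
500,20932.8,L.mol-1.cm-1
510,20035.2,L.mol-1.cm-1
520,24202.4,L.mol-1.cm-1
530,39956.8,L.mol-1.cm-1
540,53236,L.mol-1.cm-1
550,43016,L.mol-1.cm-1
560,32613.2,L.mol-1.cm-1
570,44496,L.mol-1.cm-1
580,50104,L.mol-1.cm-1
590,14400.8,L.mol-1.cm-1
600,3200,L.mol-1.cm-1
610,1506,L.mol-1.cm-1
620,942,L.mol-1.cm-1
630,610,L.mol-1.cm-1
640,442,L.mol-1.cm-1
650,368,L.mol-1.cm-1
660,319.6,L.mol-1.cm-1
670,294,L.mol-1.cm-1
680,277.6,L.mol-1.cm-1
690,276,L.mol-1.cm-1
700,290,L.mol-1.cm-1
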