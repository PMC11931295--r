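wavelength_nm,value,units
400,223296,L.mol-1.cm-1
410,303956,L.mol-1.cm-1
420,407560,L.mol-1.cm-1
430,528600,L.mol-1.cm-1
440,413280,L.mol-1.cm-1
450,103292,L.mol-1.cm-1
460,23388.8,L.mol-1.cm-1
470,16156.4,L.mol-1.cm-1
480,14550,L.mol-1.cm-1
490,16684,L.mol-1.cm-1
500,20862,L.mol-1.cm-1
510,25773.6,L.mol-1.cm-1
520,31589.6,L.mol-1.cm-1
530,39036.4,L.mol-1.cm-1
540,46592,L.mol-1.cm-1
550,53412,L.mol-1.cm-1
560,53788,L.mol-1.cm-1
570,45072,L.mol-1.cm-1
580,37020,L.mol-1.cm-1
590,28324.4,L.mol-1.cm-1
600,14677.2,L.mol-1.cm-1
610,9443.6,L.mol-1.cm-1
620,6509.6,L.mol-1.cm-1
630,5148.8,L.mol-1.cm-1
640,4345.2,L.mol-1.cm-1
650,3750.12,L.mol-1.cm-1
660,3226.56,L.mol-1.cm-1
670,2795.12,L.mol-1.cm-1
680,2407.92,L.mol-1.cm-1
690,2051.96,L.mol-1.cm-1
700,1794.28,L.mol-1.cm-1
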