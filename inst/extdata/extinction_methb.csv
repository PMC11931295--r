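wavelength_nm,value,units
400,600000,L.mol-1.cm-1
410,560000,L.mol-1.cm-1
420,240000,L.mol-1.cm-1
430,120000,L.mol-1.cm-1
440,56000,L.mol-1.cm-1
450,38000,L.mol-1.cm-1
460,31200,L.mol-1.cm-1
470,29200,L.mol-1.cm-1
480,30400,L.mol-1.cm-1
490,33600,L.mol-1.cm-1
500,36160,L.mol-1.cm-1
510,34800,L.mol-1.cm-1
520,30640,L.mol-1.cm-1
530,28000,L.mol-1.cm-1
540,25640,L.mol-1.cm-1
550,22000,L.mol-1.cm-1
560,18840,L.mol-1.cm-1
570,17200,L.mol-1.cm-1
580,16800,L.mol-1.cm-1
590,13600,L.mol-1.cm-1
600,12240,L.mol-1.cm-1
610,12800,L.mol-1.cm-1
620,14400,L.mol-1.cm-1
630,15000,L.mol-1.cm-1
640,12800,L.mol-1.cm-1
650,9200,L.mol-1.cm-1
660,4400,L.mol-1.cm-1
670,3200,L.mol-1.cm-1
680,2520,L.mol-1.cm-1
690,2080,L.mol-1.cm-1
700,1760,L.mol-1.cm-1
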