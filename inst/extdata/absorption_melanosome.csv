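wavelength_nm,value,units
400,1128.273,cm-1
410,1035.369,cm-1
420,952.084,cm-1
430,877.229,cm-1
440,809.781,cm-1
450,748.865,cm-1
460,693.722,cm-1
470,643.698,cm-1
480,598.223,cm-1
490,556.802,cm-1
500,519,cm-1
510,484.439,cm-1
520,452.784,cm-1
530,423.743,cm-1
540,397.057,cm-1
550,372.495,cm-1
560,349.855,cm-1
570,328.957,cm-1
580,309.638,cm-1
590,291.755,cm-1
600,275.18,cm-1
610,259.798,cm-1
620,245.505,cm-1
630,232.208,cm-1
640,219.825,cm-1
650,208.279,cm-1
660,197.501,cm-1
670,187.432,cm-1
680,178.013,cm-1
690,169.195,cm-1
700,160.932,cm-1
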