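wavelength_nm,xbar,ybar,zbar
400,0.0143,4e-04,0.0679
410,0.0435,0.0012,0.2074
420,0.1344,0.004,0.6456
430,0.2839,0.0116,1.3856
440,0.3483,0.023,1.7471
450,0.3362,0.038,1.7721
460,0.2908,0.06,1.6692
470,0.1954,0.091,1.2876
480,0.0956,0.139,0.813
490,0.032,0.208,0.4652
500,0.0049,0.323,0.272
510,0.0093,0.503,0.1582
520,0.0633,0.71,0.0782
530,0.1655,0.862,0.0422
540,0.2904,0.954,0.0203
550,0.4334,0.995,0.0087
560,0.5945,0.995,0.0039
570,0.7621,0.952,0.0021
580,0.9163,0.87,0.0017
590,1.0263,0.757,0.0011
600,1.0622,0.631,8e-04
610,1.0026,0.503,3e-04
620,0.8544,0.381,2e-04
630,0.6424,0.265,0
640,0.4479,0.175,0
650,0.2835,0.107,0
660,0.1649,0.061,0
670,0.0874,0.032,0
680,0.0468,0.017,0
690,0.0227,0.0082,0
700,0.0114,0.0041,0
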