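chromophore,file,units,source
HbO,extinction_hbo.csv,L.mol-1.cm-1,standard compiled oxy/deoxyhemoglobin molar extinction tabulation (tetramer basis)
HbR,extinction_hbr.csv,L.mol-1.cm-1,standard compiled oxy/deoxyhemoglobin molar extinction tabulation (tetramer basis)
metHb,extinction_methb.csv,L.mol-1.cm-1,synthetic compilation of standard aquomethemoglobin tabulations (tetramer basis)
melanosome,absorption_melanosome.csv,cm-1,power-law melanosome approximation 519*(lambda/500)^-3.48
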