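# Specific absorption coefficients of oxy- and deoxy-hemoglobin,
# natural-log convention, units 1/(cm*uM): mua = E %*% c with c in uM.
# Compiled from standard literature tabulations of molar extinction
# coefficients (decadic, 1/(cm*M)) via E = ln(10) * eps * 1e-6.
# Replace with any table holding the same columns to use a different source.
wavelength_nm,HbO2,HHb
685,0.000663,0.005543
785,0.001704,0.002437
830,0.002243,0.001596
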