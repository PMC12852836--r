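# Molar extinction coefficients of human oxy-/deoxy-hemoglobin
# (L mol^-1 cm^-1), approximating a standard tabulated compilation.
# These values are configuration: override with your own CSV of the same
# layout for quantitative work. The pipeline requires the 532 and 558 nm
# rows; the rest give the visible-band context of the two spectra.
wavelength_nm,eps_hbo2,eps_hbr
500,20932,20862
510,25773,24103
520,30885,27296
530,39956,39437
532,44480,40584
540,53236,46592
545,51156,50676
550,43016,52276
555,36818,53412
558,33128,53110
560,32620,53292
570,44584,49536
576,55540,46150
580,50104,37020
590,16684,26600
600,3200,14677
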