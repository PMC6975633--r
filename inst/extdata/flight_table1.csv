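"duration_days","duration_sd_days","bmd_change_pct","dispersion_pct","n","source"
11,,0,,69,"LeBlanc2000+Lang2004"
132,,-1.3,,1,"LeBlanc2000"
132,,-6,,1,"LeBlanc2000"
145,,-4.5,,1,"LeBlanc2000"
150,30,-9.4,6.4,16,"Lang2004"
169,,-3.5,,1,"LeBlanc2000"
169,,-3.1,,1,"LeBlanc2000"
176,,-11.4,,1,"LeBlanc2000"
176,,-5.3,,1,"LeBlanc2000"
181,47,-6.8,1.1,46,"Sibonga2007"
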