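"sex","ethnicity","age_min","age_max","premission_bmd_g_cm2"
"male","non-Hispanic white",30,39,0.8864
"male","non-Hispanic black",30,39,1.0043
"male","Mexican-American",30,39,0.9205
"male","non-Hispanic white",40,49,0.8381
"male","non-Hispanic black",40,49,0.9333
"male","Mexican-American",40,49,0.8693
"female","non-Hispanic white",30,39,0.8239
"female","non-Hispanic black",30,39,0.912
"female","Mexican-American",30,39,0.8665
"female","non-Hispanic white",40,49,0.7912
"female","non-Hispanic black",40,49,0.9134
"female","Mexican-American",40,49,0.848
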