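"sex","ethnicity","age_min","age_max","duration_days","t_score"
"male","non-Hispanic white",30,39,400,-0.91
"male","non-Hispanic black",30,39,400,-0.08
"male","Mexican-American",30,39,400,-0.67
"male","non-Hispanic white",40,49,400,-1.25
"male","non-Hispanic black",40,49,400,-0.58
"male","Mexican-American",40,49,400,-1.03
"female","non-Hispanic white",30,39,400,-1.35
"female","non-Hispanic black",30,39,400,-0.73
"female","Mexican-American",30,39,400,-1.05
"female","non-Hispanic white",40,49,400,-1.58
"female","non-Hispanic black",40,49,400,-0.72
"female","Mexican-American",40,49,400,-1.18
"male","non-Hispanic white",30,39,600,-1.38
"male","non-Hispanic black",30,39,600,-0.62
"male","Mexican-American",30,39,600,-1.16
"male","non-Hispanic white",40,49,600,-1.7
"male","non-Hispanic black",40,49,600,-1.08
"male","Mexican-American",40,49,600,-1.49
"female","non-Hispanic white",30,39,600,-1.79
"female","non-Hispanic black",30,39,600,-1.22
"female","Mexican-American",30,39,600,-1.52
"female","non-Hispanic white",40,49,600,-2.01
"female","non-Hispanic black",40,49,600,-1.2
"female","Mexican-American",40,49,600,-1.64
"male","non-Hispanic white",30,39,1000,-2.2
"male","non-Hispanic black",30,39,1000,-1.49
"male","Mexican-American",30,39,1000,-1.96
"male","non-Hispanic white",40,49,1000,-2.43
"male","non-Hispanic black",40,49,1000,-1.88
"male","Mexican-American",40,49,1000,-2.25
"female","non-Hispanic white",30,39,1000,-2.5
"female","non-Hispanic black",30,39,1000,-2.01
"female","Mexican-American",30,39,1000,-2.26
"female","non-Hispanic white",40,49,1000,-2.69
"female","non-Hispanic black",40,49,1000,-1.99
"female","Mexican-American",40,49,1000,-2.38
"male","non-Hispanic white",30,39,1200,-2.48
"male","non-Hispanic black",30,39,1200,-1.86
"male","Mexican-American",30,39,1200,-2.29
"male","non-Hispanic white",40,49,1200,-2.73
"male","non-Hispanic black",40,49,1200,-2.23
"male","Mexican-American",40,49,1200,-2.57
"female","non-Hispanic white",30,39,1200,-2.8
"female","non-Hispanic black",30,39,1200,-2.34
"female","Mexican-American",30,39,1200,-2.58
"female","non-Hispanic white",40,49,1200,-2.93
"female","non-Hispanic black",40,49,1200,-2.33
"female","Mexican-American",40,49,1200,-2.68
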