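model,endpoint,scenario,year,deaths_million
linear,AD,HIST,2010,0.37
linear,AD,CLE,2020,0.32
linear,AD,CLE,2030,0.21
linear,AD,CLE,2040,0.19
linear,AD,CLE,2049,0.18
linear,AD,MFR,2020,0.32
linear,AD,MFR,2030,0.10
linear,AD,MFR,2040,0.07
linear,AD,MFR,2049,0.06
linear,CD,HIST,2010,3.08
linear,CD,CLE,2020,2.96
linear,CD,CLE,2030,2.02
linear,CD,CLE,2040,1.87
linear,CD,CLE,2049,1.80
linear,CD,MFR,2020,2.97
linear,CD,MFR,2030,0.97
linear,CD,MFR,2040,0.71
linear,CD,MFR,2049,0.63
linear,total,HIST,2010,3.45
linear,total,CLE,2020,3.28
linear,total,CLE,2030,2.23
linear,total,CLE,2040,2.06
linear,total,CLE,2049,1.98
linear,total,MFR,2020,3.29
linear,total,MFR,2030,1.07
linear,total,MFR,2040,0.78
linear,total,MFR,2049,0.69
nonlinear,LC,HIST,2010,0.17
nonlinear,LC,CLE,2020,0.22
nonlinear,LC,CLE,2030,0.19
nonlinear,LC,CLE,2040,0.22
nonlinear,LC,CLE,2049,0.23
nonlinear,LC,MFR,2020,0.23
nonlinear,LC,MFR,2030,0.10
nonlinear,LC,MFR,2040,0.09
nonlinear,LC,MFR,2049,0.09
nonlinear,COPD,HIST,2010,0.29
nonlinear,COPD,CLE,2020,0.29
nonlinear,COPD,CLE,2030,0.26
nonlinear,COPD,CLE,2040,0.33
nonlinear,COPD,CLE,2049,0.34
nonlinear,COPD,MFR,2020,0.29
nonlinear,COPD,MFR,2030,0.14
nonlinear,COPD,MFR,2040,0.14
nonlinear,COPD,MFR,2049,0.14
nonlinear,IHD,HIST,2010,0.47
nonlinear,IHD,CLE,2020,0.60
nonlinear,IHD,CLE,2030,0.54
nonlinear,IHD,CLE,2040,0.65
nonlinear,IHD,CLE,2049,0.67
nonlinear,IHD,MFR,2020,0.60
nonlinear,IHD,MFR,2030,0.34
nonlinear,IHD,MFR,2040,0.34
nonlinear,IHD,MFR,2049,0.33
nonlinear,stroke,HIST,2010,0.15
nonlinear,stroke,CLE,2020,0.18
nonlinear,stroke,CLE,2030,0.15
nonlinear,stroke,CLE,2040,0.19
nonlinear,stroke,CLE,2049,0.19
nonlinear,stroke,MFR,2020,0.18
nonlinear,stroke,MFR,2030,0.07
nonlinear,stroke,MFR,2040,0.07
nonlinear,stroke,MFR,2049,0.06
nonlinear,LRI,HIST,2010,0.07
nonlinear,LRI,CLE,2020,0.09
nonlinear,LRI,CLE,2030,0.08
nonlinear,LRI,CLE,2040,0.10
nonlinear,LRI,CLE,2049,0.11
nonlinear,LRI,MFR,2020,0.09
nonlinear,LRI,MFR,2030,0.04
nonlinear,LRI,MFR,2040,0.04
nonlinear,LRI,MFR,2049,0.04
nonlinear,total,HIST,2010,1.75
nonlinear,total,CLE,2020,2.11
nonlinear,total,CLE,2030,1.78
nonlinear,total,CLE,2040,2.15
nonlinear,total,CLE,2049,2.23
nonlinear,total,MFR,2020,2.12
nonlinear,total,MFR,2030,1.07
nonlinear,total,MFR,2040,1.08
nonlinear,total,MFR,2049,1.05
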