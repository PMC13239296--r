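population,cohort,n,subset,pl_pct,ar,pa_pct,ho,he,fis
warm,wild,98,neutral,36.626,1.038,20.975,0.005,0.006,0.200
warm,hatchery,62,neutral,17.960,NA,3.784,0.004,0.006,0.183
cool,wild,101,neutral,54.586,1.090,26.491,0.014,0.017,0.175
cool,hatchery,36,neutral,27.646,NA,3.784,0.011,0.016,0.206
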