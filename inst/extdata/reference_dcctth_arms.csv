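arm,n,baseline_mean,baseline_sd,month12_mean,month12_sd,change_mean,change_sd,pct_change_mean,pct_change_sd
placebo,8,366,76,378,73,12,21,3,6
teriparatide,12,349,49,420,78,71,46,20,13
romosozumab,11,364,36,558,77,194,66,53,18
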