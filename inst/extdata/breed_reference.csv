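breed,mean_diameter_um,diameter_cv_pct,avg_perimeter_per_100um,perimeter_pm_um,avg_scales_per_100um,scales_pm,D_1e8_cm2_per_s,D_stderr_1e8_cm2_per_s
Leicester,22,11.7,309,27,6,1.0,0.091,0.001
Ryeland,31,12.7,510,44,10,1.1,0.133,0.001
Herdwick,66,54.0,NA,NA,NA,NA,NA,NA
Dartmoor,72,22.5,754,39,16,1.2,0.592,0.011
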