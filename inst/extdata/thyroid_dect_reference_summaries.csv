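feature,energy_keV,benign_n,benign_mean,benign_sd,malignant_n,malignant_mean,malignant_sd,printed_p,printed_cutoff_direction,printed_cutoff,printed_sensitivity_pct,printed_specificity_pct,printed_auc,regression_target
histogram.mean,40,14,1124.8,39.6,20,1091.3,52.3,0.052,NA,NA,NA,NA,0.682,TRUE
histogram.mean,60,14,1091.9,26.2,20,1059.8,94.5,0.163,NA,NA,NA,NA,0.664,TRUE
histogram.mean,80,14,1085.7,18.5,20,1071.9,9.4,0.019,<,1080.9,57.1,85.0,0.771,TRUE
histogram.median,40,14,1124.8,39.2,20,1099.7,27.1,0.034,<,1112.0,64.3,85.0,0.686,TRUE
histogram.median,60,14,1092.8,26.0,20,1072.6,39.4,0.103,NA,NA,NA,NA,0.679,TRUE
histogram.median,80,14,1086.7,18.6,20,1071.9,9.5,0.014,<,1080.9,71.0,75.0,0.771,TRUE
glcm.contrast,40,14,23.6,18.9,20,18.0,12.5,0.309,NA,NA,NA,NA,0.629,FALSE
glcm.contrast,60,14,21.3,20.1,20,17.2,27.1,0.635,NA,NA,NA,NA,0.629,FALSE
glcm.contrast,80,14,18.5,15.3,20,8.4,4.3,0.031,<,15.12,50.0,85.0,0.693,TRUE
glgm.skewness,40,14,36.3,12.3,20,28.6,7.6,0.030,<,37.00,50.0,85.0,0.696,TRUE
glgm.skewness,60,14,36.0,12.2,20,28.8,7.4,0.064,NA,NA,NA,NA,0.671,TRUE
glgm.skewness,80,14,36.4,12.0,20,28.8,7.4,0.030,<,29.49,78.6,65.0,0.696,TRUE
glgm.MGR,40,14,5.792,3.559,20,9.340,5.805,0.035,>,3.301,95.0,35.7,0.689,FALSE
glgm.MGR,60,14,5.041,2.880,20,7.993,4.479,0.038,>,3.692,85.0,50.0,0.693,TRUE
glgm.MGR,80,14,4.850,2.696,20,7.615,4.199,0.038,>,3.639,85.0,50.0,0.704,TRUE
glgm.VGR,40,14,19974.2,10745.3,20,30478.1,16424.1,0.044,>,15036,85.0,42.4,0.689,TRUE
glgm.VGR,60,14,18824.2,10530.9,20,28949.7,15235.9,0.039,>,12098,95.0,35.7,0.696,TRUE
glgm.VGR,80,14,17957.5,10154.8,20,28800.9,15431.2,0.028,>,14288,85.0,50.0,0.721,TRUE
iodine_content,NA,14,0.54,0.849,20,0.437,0.542,0.48,NA,NA,NA,NA,0.564,FALSE
normalized_slope,NA,14,0.836,0.924,20,0.667,0.609,0.67,NA,NA,NA,NA,0.571,FALSE
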