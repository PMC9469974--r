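label,type,d_low,d_high,d_mean,d_sd,source_tag
typical_density,range,0.01,0.05,NA,NA,lit_tigrina_review
high_density,range,0.1,0.25,NA,NA,lit_tigrina_review
high_density_camera,mean_sd,NA,NA,0.15,0.08,lit_camera_trap
fragmented_landscape,range,0.07,0.13,NA,NA,lit_tigrina_review
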