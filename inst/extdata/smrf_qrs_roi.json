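{"name":"smrf_qrs_roi","bin_length_s":0.032,"grid_fs":500,"values":[0.05,0.05,0.05,0.05,0.05,0.06,0.08,0.1,0.12,0.12,0.12,0.1,0.1,0.12,0.3,0.6,0.85,0.95,1,1,1,1,0.95,0.85,0.7,0.55,0.45,0.4,0.38,0.36,0.36,0.38,0.4,0.4,0.38,0.35,0.3,0.25,0.2,0.15,0.1,0.08,0.06,0.05,0.05,0.05,0.05,0.05,0.05,0.05],"landmarks":[106,196,246,338,672]}
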