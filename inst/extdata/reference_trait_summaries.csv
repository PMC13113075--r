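condition,n_total,intensity_mean,intensity_sd,duration_mean,duration_sd,pitch_mean,pitch_sd,n_pitch,f2_mean,f2_sd
pain,475,82.98,7.09,0.94,0.48,267.99,172.49,423,2275.29,252.02
hunger,454,73.02,6.64,0.64,0.45,221.32,124.33,385,1848.59,237.92
thirst,351,73.72,5.40,0.52,0.27,155.23,135.65,340,1927.01,287.97
cold,246,74.36,5.01,1.14,0.78,151.42,89.01,246,1768.13,148.31
heat,223,76.83,5.69,0.34,0.14,301.69,102.99,146,1988.93,206.36
normal,472,72.76,5.76,0.49,0.29,171.53,133.70,440,1900.99,304.94
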