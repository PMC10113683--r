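fraction,median_mm,iqr_low_mm,iqr_high_mm,prediction_rate_pct
1,2.16,1.52,2.99,75.5
2,2.17,1.64,2.75,65.2
3,2.36,1.83,2.90,65.7
4,2.42,1.74,3.23,64.2
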