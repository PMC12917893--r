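# Sentinel carried by every metric of an invalid 30-min window.
HRV_SENTINEL <- -1

# The nine per-window HRV metrics of the sequence feature family.
hrv_metric_names <- c("meanNN", "SDNN", "RMSSD", "NN50", "pNN50",
                      "LF", "HF", "LF_HF", "TP")
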