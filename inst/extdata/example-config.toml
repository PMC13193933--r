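# Interference-model tuning for a hypothetical endurance-susceptible athlete.
# Flat key = value pairs; CLI flags override these values.
rfd0 = 12500      # baseline peak RFD, N/s
kappa = 0.8       # maximal fractional RFD loss
alpha = 0.4       # per-minute rate constant (more susceptible than default 0.3)
d0 = 2            # onset delay, minutes
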