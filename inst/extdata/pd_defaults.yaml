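# Calibrated default PD parameters (regenerate with scripts/calibrate_pd.R)
kg: 0.274
EmaxS: 1.19
EC50S: 0.7
EmaxA: 1.0
EC50A: 50.0
alpha: 1.35
kin: 1.0
kout: 1.44
V0: 1.0
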