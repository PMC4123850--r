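# Denali golden eagle nest-management defaults
# occupancy dynamics
p_c = 0.2315
p_n = 0.9427
p_s = 0.9573
# fledging-success logit (moderate-disturbance model)
beta_int = -0.75
beta_hare = 0.06
beta_dist = -0.2
# management constants
hare = 9.4
n_sites = 25
alpha = 0.85
discount = 0.98
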