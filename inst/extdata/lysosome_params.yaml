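j_clc: 2.45
j_tpc: 16.0
j_clc_leak: 0.02
j_tpc_leak: 0.02
PO_max: 0.016
PO_mean: 31.8888108
PO_sd: 0.55
V_ls: 2.4
J_ls_j: 0.001
J_ls_i: 0.02
naadp: 1.0
uptake_blocked: no
release_blocked: no
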