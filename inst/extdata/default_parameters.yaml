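g_cen: 62.0
g_sur: 48.0
g_rect: 7.2
g_cort: 1.0
g_GC: 4.21
r_cen: 0.4
r_sur: 1.1
r_cort: 2.8
tau_on: 11.0
tau_off: 9.0
tau_cort: 10.0
p0_sub: 1.94
p0_stage1: -25.5
p0_late: 0.646
m: 2
patch_side: 2.0
cortical_grid_spacing: 0.1
opposite_sign_spacing: 0.1
elongation_spacing: 0.75
surround_enabled: no
subcortical_rectification_enabled: no
spontaneous_lgn_rate: 14.0
resting_minus_threshold_stage1: derived
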