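# Shared fixtures: parameter sets and small networks built once per file.

tbl_params <- model_parameters()                 # tabulated working values
cal_params <- calibrated_parameters()            # full-precision chain
cal_params6 <- calibrated_parameters(m = 6)

net_single <- build_network(cal_params, cortical_stages = 1,
                            single_cell = TRUE)
net_single6 <- build_network(cal_params6, cortical_stages = 1,
                             single_cell = TRUE)

# coarse population network (9 x 9 cortical grid) for fast population tests
net_coarse <- build_network(cal_params, cortical_stages = 1,
                            grid_spacing = 0.25)
net_full3 <- build_network(cal_params, cortical_stages = 3,
                           grid_spacing = 0.25)

rel_diff <- function(a, b) abs(a - b) / pmax(abs(a), abs(b))
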