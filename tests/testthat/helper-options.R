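# Coarse discretization for chain-level tests: relative metrics (flatness,
# symmetry, response shapes) converge well before the reference grids.
coarse_opts <- sim_options(n_slabs = 120, n_K = 60, n_angle = 61,
                           grid_spacing = 0.5, grid_halfwidth = 12)
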