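# shared fixtures: morphologies in SI units and the default constants
morphs <- load_morphology_table()
male <- morphs[["Peregrine falcon (male)"]]
female <- morphs[["Peregrine falcon (female)"]]
mallard <- morphs[["Mallard"]]
starling <- morphs[["Common starling"]]
aero <- aero_params()

falcon_sexes <- c("Peregrine falcon (male)", "Peregrine falcon (female)")

# quick engagement config for unit-level tests (coarser step, short timeout)
quick_cfg <- function(...) {
  engagement_config(dt = 0.005, timeout = 30, head_start = 2, ...)
}
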