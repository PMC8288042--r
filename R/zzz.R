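.onLoad <- function(libname, pkgname) {
  register_extra_dynamics("rat_ca_handling", rat_ca_handling)
  # V as a scaled readout of one gate (threshold fixtures)
  register_extra_dynamics("gate_readout", function(t, y, ctx) {
    p <- ctx$model$params
    list(dV_add = p$readout_gain * ctx$dx[[p$readout_gate]])
  })
  invisible()
}
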