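# Model registration at package load.

# ten Tusscher-Panfilov (epicardial, Na/K-clamped) resting fixed point:
# 5000 ms unstimulated Rush-Larsen settle from the published initial
# conditions, then a Levenberg-Marquardt polish of the steady-state
# equations (V, Ca subsystem; gates at their steady values). The residual
# |d state/dt| at this vector is below 1e-13 per ms.
.tt_rest_values <- c(
  -86.2129488287395, 0.000183731779983912, 0.481393479610453,
  0.00301563424792082, 0.00139167873519006, 0.770856429925287,
  0.770856429925287, 2.95796847792768e-05, 0.999922020974547,
  0.999554929392028, 0.999998239666528, 0.999998226563803,
  2.05140020190689e-08, 3.26885923003213e-05, 0.297697117352351,
  8.56431218517845e-05, 0.998120383600271
)

.onLoad <- function(libname, pkgname) {
  register_ionic_model(phenomenological_model())
  register_ionic_model(ionic_model_spec(
    name = "ten_tusscher", n_states = 17,
    rest_state = .tt_rest_values,
    rates = ten_tusscher_rates,
    gating_indices = .tt_gating,
    state_names = .tt_state_names
  ))
  invisible()
}
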