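# Mean control coefficients of the bundled maize coleoptile fits,
# used as the canonical "realistic" parameter set throughout the suite.
mean_control_params <- function() {
  fit_params(A = 15.4e-7, B = 0.0009, C = 0.083, D = 12.9e-5, t_e = 22205)
}

# Smooth compactly supported bump pair: both signals vanish at the record
# edges, the regime in which discrete cross-correlation identities hold to
# near machine precision.
bump_pair <- function(dt = 2, span = 2000, shift = 200) {
  t <- seq(0, span, by = dt)
  f <- growth_ts(t, exp(-((t - 0.45 * span) / (0.075 * span))^2), "pH")
  g <- growth_ts(t, 5 * exp(-((t - 0.45 * span - shift) / (0.09 * span))^2),
                 "elongation")
  list(f = f, g = g)
}

rel_err <- function(x, ref) abs(x - ref) / abs(ref)
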