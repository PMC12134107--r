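# Shared fixtures, all built in code.

# One-condition grid at the reference point of the factor space.
ref_condition <- function() {
  make_conditions_grid(temperature_c = 50, velocity_ms = 0.7,
                       intensity_wm2 = 3500)
}

# Noise-free exponential decay curve in the Fick one-term form.
one_term_curve <- function(s = 1e-4, dt = 300, mr_stop = 0.01) {
  t_max <- ceiling(log((8 / pi^2) / mr_stop) / s)
  t_s <- seq(0, t_max, by = dt)
  tibble::tibble(t_s = t_s, mr = (8 / pi^2) * exp(-s * t_s))
}

# Midilli-Kucuk truth from the parameter-recovery example, sampled where the
# curve is strictly positive.
midilli_example_curve <- function() {
  true <- c(a = 0.98, k = 0.004, n = 1.1, b = -1e-6)
  t_s <- seq(0, 600, by = 10)
  list(params = true,
       curve = tibble::tibble(
         t_s = t_s, mr = evaluate_model("midilli_kucuk", true, t_s)))
}

# Small quality table with zero noise for monotonicity checks.
noiseless_quality <- function() {
  spec <- quality_surface_spec()
  for (nm in names(spec$surfaces)) spec$surfaces[[nm]]$sd <- 0
  simulate_quality_table(make_conditions_grid(), spec, seed = 1)
}
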