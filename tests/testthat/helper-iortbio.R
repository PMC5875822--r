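# Shared fixtures, built in code.

ib_model <- function() fit_radial_dose(ib_anchors_50kv())

# Independent series oracle for the protraction factor:
# G(theta) = 2 * sum_{k>=0} (-theta)^k / (k+2)!
G_series <- function(theta, K = 80) {
  k <- 0:K
  2 * sum((-theta)^k / factorial(k + 2))
}

# Scenario shorthand for the standard 50 kV study conditions.
std_scenario <- function(prescription = 20, extent_mm = 3, cancer = "C1",
                         normal = "N1", kind = "half_gaussian", f0 = 1e-4,
                         beam = "50kV", model = ib_model()) {
  scenario_spec(beam_spec(beam), prescription, cell_params(cancer),
                cell_params(normal), density_profile(kind, extent_mm, f0),
                model)
}
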