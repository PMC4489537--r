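# Shared fixtures: the two benchmark setups and small phantoms built in
# code. Materials come from the bundled optical-constants table.

pet_material <- function() ei_materials("PET")
peek_material <- function() ei_materials("PEEK")
water_material <- function() ei_materials("water")

wire_setup <- function() {
  curve <- wire_benchmark_curve()
  list(geometry = wire_benchmark_geometry(), curve = curve,
       wp = working_point(curve, 0.5, "lower"),
       wp_upper = working_point(curve, 0.5, "upper"))
}

petal_setup <- function() {
  curve <- petal_benchmark_curve()
  list(geometry = petal_benchmark_geometry(), curve = curve,
       wp = working_point(curve, 0.5, "lower"))
}

# smooth, compactly supported thickness bump: gentle gradients, so the
# discrete derivative identities hold to high order
gaussian_bump_map <- function(amplitude = 50, width_um = 300,
                              shape = c(256L, 64L), step_y = 20, step_x = 46,
                              material = pet_material()) {
  y <- (seq_len(shape[1]) - 1) * step_y
  x <- (seq_len(shape[2]) - 1) * step_x
  vals <- amplitude * exp(-outer((y - mean(y))^2 / (2 * width_um^2),
                                 (x - mean(x))^2 / (2 * width_um^2), `+`))
  thickness_map(vals, step_y, step_x, material)
}

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
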