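# shared fixtures, memoised so expensive simulations run once per session

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

small_tree <- function() memo("small_tree",
  synthetic_tree(42, n_fu = 6, n_fruits = 21, n_sprouts = 8))

forcing_ns <- function() memo("forcing_ns",
  generate_synthetic_forcing(42, days = 150, profile = "NS"))

forcing_ss <- function() memo("forcing_ss",
  generate_synthetic_forcing(42, days = 150, profile = "SS"))

# the 13-scenario suite on the full-size study tree (used by the
# conservation and qualitative-pattern acceptance checks)
scenario_suite <- function() memo("scenario_suite", {
  run_scenarios(synthetic_tree(1), seed = 1, days = 150)
})

# single-FU tree at wide spacing, for interception tests without
# neighbour-crown shading
lone_unit_tree <- function(radius = 0.4, leaf_area = 1.0) {
  p <- default_params(spacing = c(100, 100))
  tr <- synthetic_tree(7, n_fu = 1, n_fruits = 1, n_sprouts = 1,
                       crown_radius = 0.5, crown_base = 1.2, crown_top = 2.4,
                       fu_semiaxes = rep(radius, 3), params = p)
  tr$fu <- tr$fu[!tr$fu$is_ws, ]
  tr$fu$x <- 0; tr$fu$y <- 0; tr$fu$z <- 1.8
  tr$fu$ax <- tr$fu$ay <- tr$fu$az <- radius
  tr$fu$leaf_area <- leaf_area
  tr$axes <- tr$axes[is.na(tr$axes$fu_id) | tr$axes$fu_id == 1, ]
  tr$axes$id <- seq_len(nrow(tr$axes))
  tr$fu$axis_id <- nrow(tr$axes)
  tr
}

# minimal hand-built tree: n units on symmetric branches off one trunk
toy_tree <- function(n = 2, leaf_area = 0.5) {
  ang <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  fu <- data.frame(
    id = seq_len(n), x = cos(ang), y = sin(ang), z = 2,
    ax = 0.3, ay = 0.3, az = 0.25,
    leaf_area = leaf_area, n_fruits = 3L, n_shoots = 8L,
    axis_id = NA_integer_, is_ws = FALSE)
  axes <- data.frame(id = 1L, parent = 0L, x = 0, y = 0, z = 1,
                     length = 1, diameter = 0.08, fu_id = NA_integer_)
  for (i in seq_len(n)) {
    axes <- rbind(axes, data.frame(
      id = i + 1L, parent = 1L, x = fu$x[i], y = fu$y[i], z = fu$z[i],
      length = sqrt(2), diameter = 0.02, fu_id = i))
    fu$axis_id[i] <- i + 1L
  }
  structure(list(fu = fu, axes = axes, spacing = c(100, 100),
                 crown = c(radius = 1.5, base = 1, top = 3)),
            class = c("orchard_tree", "list"))
}
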