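# Shared fixtures, built lazily and cached for the session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# three-tube wall phantom with analytic ground truth
wall_phantom <- function() fixture("wall_phantom", function()
  generate_phantom(standard_wall_phantom(), seed = 1))

# straight 50-mm tube along z, 0.4-mm voxels
long_tube_phantom <- function() fixture("long_tube", function() {
  tube <- tube_spec(start = c(12.8, 12.8, 3), end = c(12.8, 12.8, 53),
                    lumen_radius = 2, wall_thickness = 1)
  generate_phantom(phantom_spec(grid_shape = c(64, 64, 140), spacing = 0.4,
                                tubes = list(tube)), seed = 1)
})

# one bifurcation: trunk (generation 0) splitting into two children
y_phantom <- function() fixture("y_phantom", function() {
  trunk <- tube_spec(start = c(12.8, 12.8, 3), end = c(12.8, 12.8, 13),
                     lumen_radius = 2, wall_thickness = 1,
                     generation_label = 0L)
  c1 <- tube_spec(start = c(12.8, 12.8, 13), end = c(7.3, 12.8, 21),
                  lumen_radius = 1.5, wall_thickness = 0.9,
                  generation_label = 1L)
  c2 <- tube_spec(start = c(12.8, 12.8, 13), end = c(18.3, 12.8, 21),
                  lumen_radius = 1.5, wall_thickness = 0.9,
                  generation_label = 1L)
  generate_phantom(phantom_spec(grid_shape = c(64, 64, 64), spacing = 0.4,
                                tubes = list(trunk, c1, c2)), seed = 1)
})

# pure-noise modeling data: 10 uninformative covariates, fair-coin outcome
noise_cohort <- function(n = 200, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 10), n, 10)
  data.frame(
    age = X[, 1], bmi = X[, 2], packyears = X[, 3],
    smoking_status = ifelse(X[, 4] > 0, "current", "former"),
    in950 = exp(X[, 5]), ei_ratio = X[, 6], pi10 = X[, 7],
    v8 = X[, 8], v9 = X[, 9], v10 = X[, 10],
    copd = rbinom(n, 1, 0.5) == 1
  )
}

noise_covariates <- c("age", "bmi", "packyears", "smoking_current",
                      "log_in950", "ei_ratio", "pi10", "v8", "v9", "v10")

# brute-force concordance: enumerate every case-control pair
c_statistic_bruteforce <- function(risks, outcomes) {
  y <- as.logical(outcomes)
  cases <- risks[y]; controls <- risks[!y]
  tot <- 0
  for (a in cases) for (b in controls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(controls))
}
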