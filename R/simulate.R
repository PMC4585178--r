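# default index ranges emulating flask-scale biosurfactant screens:
# OD600 up to ~1.2, protein up to ~7 g/L, surface tension falling from
# ~55 toward ~30 mN/m as activity rises, clear zone up to ~7.5 cm
default_index_ranges <- function() {
  list(biomass = c(0, 1.2), protein = c(0, 7),
       surface_tension = c(55, 30),  # decreasing in utility
       clear_zone = c(0, 7.5))
}

# substream seed for stream number `s` under global seed; keeps each index
# column's noise independent of how many other streams are drawn
substream_seed <- function(seed, s) {
  as.integer((as.numeric(seed) + 104729 * s) %% 2147483647)
}

#' Simulate a single-factor screen table with known ground truth
#'
#' Generates alternatives whose four production indices are monotone
#' transforms of a latent "true utility", plus independent Gaussian
#' measurement noise truncated at zero. Benefit indices increase linearly
#' from the low to the high end of their range with utility; surface tension
#' decreases. The true utility ordering is attached as attribute `"truth"`,
#' so ranking recovery can be scored exactly.
#'
#' @param utility positive true utilities, one per alternative (default five
#'   alternatives with geometrically decaying utilities `0.8^(0:4)`).
#' @param noise_sd measurement noise as a fraction of each index range.
#' @param seed global seed; per-index substreams are derived from it.
#' @param labels alternative names.
#' @param dropout indices of alternatives producing no biosurfactant: their
#'   clear-zone diameter is forced to 0 (emulating non-producing carbon
#'   sources).
#' @param ranges named list of index ranges, see defaults in the source.
#' @param experiment experiment name.
#' @return a [screen_table()] with attribute `"truth"` (list: `utility`,
#'   `best_index`).
#' @examples
#' tab <- simulate_screen(noise_sd = 0, seed = 1)
#' run_screen(tab)$best_index  # recovers alternative 1
#' @export
simulate_screen <- function(utility = 0.8^(0:4), noise_sd = 0.05, seed = NULL,
                            labels = NULL, dropout = integer(0),
                            ranges = default_index_ranges(),
                            experiment = "simulated screen") {
  if (length(utility) < 2 || any(!is.finite(utility)) || any(utility <= 0)) {
    validation_error("utility must be >= 2 strictly positive values")
  }
  if (noise_sd < 0) validation_error("noise_sd must be nonnegative")
  n <- length(utility)
  if (is.null(labels)) labels <- paste0("alt", seq_len(n))
  u <- utility / max(utility)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  cols <- list()
  nms <- names(default_index_ranges())
  for (s in seq_along(nms)) {
    nm <- nms[s]
    rg <- ranges[[nm]]
    mu <- rg[1] + (rg[2] - rg[1]) * u
    set.seed(substream_seed(seed, s))
    val <- mu + stats::rnorm(n, 0, noise_sd * abs(rg[2] - rg[1]))
    val <- pmax(val, 0)
    if (nm == "surface_tension") val <- pmin(pmax(val, 1), 100)
    cols[[nm]] <- val
  }
  if (length(dropout)) cols$clear_zone[dropout] <- 0
  tab <- screen_table(
    data.frame(label = labels, cols, stringsAsFactors = FALSE),
    experiment = experiment)
  attr(tab, "truth") <- list(utility = utility, best_index = which.max(utility),
                             seed = seed)
  tab
}

#' Simulate CCD responses from a known quadratic surface
#'
#' Evaluates a known coefficient vector on the coded CCD points and adds
#' i.i.d. Gaussian noise, giving a fixture with exact ground truth for
#' parameter-recovery and ANOVA tests.
#'
#' @param beta generating coefficients in the canonical order of
#'   [quadratic_model()] (length 10 for `k = 3`).
#' @param sigma response noise standard deviation.
#' @param k,alpha,n_center design parameters passed to [ccd_design()].
#' @param seed RNG seed.
#' @return list with `design` (a [ccd_design()]), `response`, `beta`,
#'   `sigma`, `seed`.
#' @examples
#' sim <- simulate_ccd(c(1, 1, 0, 0, 0, 0, 0, -1, -1, -1), sigma = 0, seed = 1)
#' fit <- fit_quadratic(sim$design, sim$response)
#' @export
simulate_ccd <- function(beta, sigma = 0, k = 3, alpha = (2^k)^0.25,
                         n_center = 6, seed = NULL) {
  if (sigma < 0) validation_error("sigma must be nonnegative")
  model <- quadratic_model(beta, k)
  des <- ccd_design(k, alpha = alpha, n_center = n_center)
  mu <- predict(model, des)
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  set.seed(substream_seed(seed, 1))
  y <- mu + stats::rnorm(length(mu), 0, sigma)
  list(design = des, response = y, beta = model$coefficients,
       sigma = sigma, seed = seed)
}
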