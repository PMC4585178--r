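# shared fixtures built in code

# the rank-derived criteria comparison matrix (biomass, protein, surface
# tension, clear zone at importance 1..4)
criteria_matrix_4 <- function() {
  judgment_matrix(rbind(
    c(1, 1/2, 1/3, 1/4),
    c(2, 1, 1/2, 1/2),
    c(3, 2, 1, 1/2),
    c(4, 2, 2, 1)),
    labels = c("biomass", "protein", "surface_tension", "clear_zone"))
}

# perfectly consistent matrix a_ij = w_i / w_j
consistent_matrix <- function(w) {
  judgment_matrix(outer(w, w, "/"))
}

# random reciprocal matrix with Saaty-scale upper triangle
random_reciprocal <- function(n, seed) {
  set.seed(seed)
  vals <- c(1/(9:2), 1:9)
  A <- diag(1, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sample(vals, 1)
    A[i, j] <- a
    A[j, i] <- 1 / a
  }
  judgment_matrix(A)
}

# mildly perturbed consistent matrix: near-consistent (CR < 0.1)
near_consistent <- function(n, seed, jitter = 0.15) {
  set.seed(seed)
  w <- runif(n, 0.5, 2)
  A <- outer(w, w, "/") * exp(matrix(0, n, n))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    A[i, j] <- A[i, j] * exp(runif(1, -jitter, jitter))
    A[j, i] <- 1 / A[i, j]
  }
  diag(A) <- 1
  judgment_matrix(A)
}

# packaged CCD run sheet (20 runs, coded levels, composite responses)
ccd_fixture <- function() {
  read_ccd_csv(ahprsm_example("ccd_runs.csv"))
}

# published actual-units regression equation for the medium factors
# (lactose, yeast extract, NaCl), canonical term order
actual_units_equation <- function() {
  quadratic_model(
    c(-0.090205, 9.13708e-3, 0.014698, 2.88754e-3,
      -4.22917e-4, -2.83125e-4, -1.08750e-4,
      -3.75750e-5, -4.37036e-4, -4.68498e-6),
    k = 3, coding = "actual")
}

expect_saaty_valid <- function(A) {
  expect_s3_class(A, "judgment_matrix")
  vals <- A[upper.tri(A)]
  admissible <- c(1/(9:2), 1:9)
  for (v in vals) {
    expect_true(any(abs(v - admissible) < 1e-9),
                label = sprintf("entry %g on Saaty scale", v))
  }
}
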