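test_that("noiseless responses from an in-span surface are recovered exactly", {
  d <- ccd_design(3)
  beta <- c(0.5, 1, -2, 0.3, 0.25, -0.1, 0, -1, -0.5, 0.8)
  y <- predict(quadratic_model(beta, 3), d)
  fit <- fit_quadratic(d, y)
  expect_equal(unname(coef(fit)), beta, tolerance = 1e-10)
  an <- rsm_anova(fit)
  expect_equal(attr(an, "r2"), 1, tolerance = 1e-10)
  expect_equal(an$ss[an$source == "Residual"], 0, tolerance = 1e-12)
})

test_that("QR-based OLS agrees with the explicit normal-equations oracle", {
  sim <- simulate_ccd(c(0.03, 0.002, 0.012, 0.005, 0.001, -0.005, -0.002,
                        -0.001, -0.004, -0.001), sigma = 0.003, seed = 11)
  fit <- fit_quadratic(sim$design, sim$response)
  X <- fit$model_matrix
  beta_ne <- solve(t(X) %*% X, t(X) %*% sim$response)   # brute-force oracle
  expect_equal(unname(coef(fit)), as.vector(beta_ne), tolerance = 1e-8)
  # residuals orthogonal to every model column
  expect_lt(max(abs(t(X) %*% fit$residuals)), 1e-8)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  d <- ccd_design(3)
  X <- as.matrix(d[, c("x1", "x2", "x3")])
  X[, 3] <- X[, 2]                     # x3 duplicates x2
  expect_error(fit_quadratic(X, rnorm(nrow(X))), "collinear")
  expect_error(fit_quadratic(X[1:8, 1:3], rnorm(8)), "more runs")
})

test_that("ANOVA additivity and degree-of-freedom bookkeeping hold on noisy fits", {
  for (seed in 1:5) {
    sim <- simulate_ccd(c(0.02, 0.01, -0.02, 0.005, 0, 0.002, -0.001,
                          -0.003, 0.001, -0.002), sigma = 0.004, seed = seed)
    fit <- fit_quadratic(sim$design, sim$response)
    an <- rsm_anova(fit)
    g <- function(s) an$ss[an$source == s]
    gd <- function(s) an$df[an$source == s]
    expect_equal(g("Model") + g("Residual"), g("Cor total"),
                 tolerance = 1e-10 * g("Cor total"))
    expect_equal(g("Lack of fit") + g("Pure error"), g("Residual"),
                 tolerance = 1e-10)
    expect_equal(gd("Model"), 9)
    expect_equal(gd("Residual"), 20 - 10)
    expect_equal(gd("Pure error"), 6 - 1)
    expect_equal(gd("Lack of fit"), 5)
  }
})

test_that("PRESS from the hat-matrix closed form equals explicit leave-one-out refits", {
  sim <- simulate_ccd(c(0.03, 0.002, 0.012, 0.005, 0.001, -0.005, -0.002,
                        -0.001, -0.004, -0.001), sigma = 0.003, seed = 23)
  fit <- fit_quadratic(sim$design, sim$response)
  an <- rsm_anova(fit)
  X <- as.matrix(sim$design[, c("x1", "x2", "x3")])
  y <- sim$response
  press_loo <- 0
  for (i in seq_along(y)) {
    f_i <- fit_quadratic(X[-i, ], y[-i])
    press_loo <- press_loo + (y[i] - predict(f_i, X[i, , drop = FALSE]))^2
  }
  expect_equal(attr(an, "press"), press_loo, tolerance = 1e-8)
})

test_that("fit statistics are invariant under affine recoding of the factors", {
  runs <- ccd_fixture()
  y <- runs$response
  X <- as.matrix(runs[, c("x1", "x2", "x3")])
  fit_coded <- fit_quadratic(X, y)
  # shift/scale into pseudo-actual units
  Xa <- sweep(sweep(X, 2, c(2, 3, 5), "*"), 2, c(5, 6, 20), "+")
  fit_actual <- fit_quadratic(Xa, y)
  an_c <- rsm_anova(fit_coded)
  an_a <- rsm_anova(fit_actual)
  expect_equal(attr(an_a, "r2"), attr(an_c, "r2"), tolerance = 1e-9)
  expect_equal(attr(an_a, "r2_adj"), attr(an_c, "r2_adj"), tolerance = 1e-9)
  expect_equal(an_a$f[an_a$source == "Model"],
               an_c$f[an_c$source == "Model"], tolerance = 1e-7)
  expect_equal(fit_actual$fitted, fit_coded$fitted, tolerance = 1e-9)
})

test_that("the packaged CCD sheet reproduces the reference ANOVA decomposition", {
  runs <- ccd_fixture()
  fit <- fit_quadratic(runs, runs$response)
  an <- rsm_anova(fit)
  ref <- read.csv(ahprsm_example("reference_anova.csv"))
  for (i in seq_len(nrow(ref))) {
    row <- an[an$source == ref$source[i], ]
    expect_equal(nrow(row), 1, label = ref$source[i])
    expect_equal(row$df, ref$df[i], label = paste(ref$source[i], "df"))
    # published SS are printed to 3 significant digits
    expect_equal(row$ss, ref$ss[i], tolerance = 6e-3,
                 label = paste(ref$source[i], "SS"))
  }
  expect_equal(round(attr(an, "r2"), 4), 0.9695)
  expect_equal(round(attr(an, "r2_adj"), 4), 0.9421)
  expect_equal(attr(an, "r2_pred"), 0.7826, tolerance = 2e-4)
  expect_equal(an$f[an$source == "Lack of fit"], 11.15, tolerance = 1e-2)
})

test_that("prediction matches a Horner-form polynomial oracle", {
  m <- actual_units_equation()
  expect_equal(predict(m, c(0, 0, 0)), unname(coef(m)[1]))
  horner <- function(x1, x2, x3) {
    b <- coef(m)
    (b[1] + x1 * (b[2] + b[5] * x2 + b[6] * x3 + b[8] * x1)
        + x2 * (b[3] + b[7] * x3 + b[9] * x2)
        + x3 * (b[4] + b[10] * x3))
  }
  for (pt in list(c(5, 6, 20), c(1, 11, 28), c(8.4, 2.6, 12))) {
    expect_equal(predict(m, pt), unname(horner(pt[1], pt[2], pt[3])),
                 tolerance = 1e-12)
  }
  # pure square evaluates as expected
  sq <- quadratic_model(c(0, 0, 0, 0, 0, 0, 0, 1, 0, 0), 3)
  expect_equal(predict(sq, c(2, 0, 0)), 4)
  expect_error(predict(m, c(1, 2)), "dimension")
})

test_that("stationary points solve the gradient system and classify correctly", {
  bowl <- quadratic_model(c(0, 0, 0, 0, 0, 0, 0, -1, -1, -1), 3)
  sp <- stationary_point(bowl)
  expect_equal(unname(sp$point), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sp$classification, "maximum")

  # published actual-units equation, lactose frozen at 5 g/L and NaCl at
  # 20 g/L: yeast-extract stationary level ~11.9 g/L (1-D linear solve)
  m <- actual_units_equation()
  sp2 <- stationary_point(m, frozen = c(x1 = 5, x3 = 20))
  expect_equal(unname(sp2$point["x2"]), 11.90796, tolerance = 1e-4)

  saddle <- quadratic_model(c(0, 0, 0, 0, 0, 0, 0, 1, -1, 1), 3)
  expect_equal(stationary_point(saddle)$classification, "saddle")

  flat <- quadratic_model(c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_error(stationary_point(flat), "singular Hessian")
})

test_that("constrained optimum agrees with a dense-grid oracle", {
  conc <- quadratic_model(c(1, 0.2, -0.1, 0, 0, 0, 0, -0.5, -0.5, -0.5), 3)
  opt <- constrained_optimum(conc)
  sp <- stationary_point(conc)
  expect_true(opt$interior)
  expect_equal(opt$point, sp$point, tolerance = 1e-12)

  lin <- quadratic_model(c(0, 1, -2, 0.5, 0, 0, 0, 0, 0, 0), 3)
  optl <- constrained_optimum(lin, lower = -1, upper = 1, n_grid = 21)
  expect_equal(unname(optl$point), c(1, -1, 1), tolerance = 1e-6)

  # boundary-maximum case checked against brute-force grid
  m <- quadratic_model(c(0, 0.5, 0.8, 0, 0, 0, -0.4, 0.2, -0.1, 0.1), 3)
  optm <- constrained_optimum(m, lower = -1.682, upper = 1.682, n_grid = 41)
  ax <- seq(-1.682, 1.682, length.out = 41)
  grid <- as.matrix(expand.grid(x1 = ax, x2 = ax, x3 = ax))
  best_grid <- max(predict(m, grid))
  expect_gte(optm$value + 1e-9, best_grid)
  cell <- diff(ax)[1]
  gi <- grid[which.max(predict(m, grid)), ]
  expect_true(all(abs(optm$point - gi) <= cell + 1e-9))
})

test_that("coding step sizes are recovered from an actual-units equation", {
  steps_true <- c(2, 3, 5)
  fm <- factor_mapping(c("a", "b", "c"), center = c(5, 6, 20),
                       step = steps_true)
  beta_actual <- coef(actual_units_equation())
  d <- ccd_design(3)
  Xa <- decode_values(as.matrix(d[, c("x1", "x2", "x3")]), fm)
  y <- predict(actual_units_equation(), Xa)
  fit_coded <- fit_quadratic(d, y)
  expect_equal(unname(estimate_steps(fit_coded, actual_units_equation())),
               steps_true, tolerance = 1e-6)
})
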