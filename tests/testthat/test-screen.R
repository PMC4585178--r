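test_that("rank_to_matrix reconstructs the criteria matrix and saturates the scale", {
  A <- rank_to_matrix(c(1, 2, 3, 4))
  expect_equal(unname(unclass(A)), unname(unclass(criteria_matrix_4())))
  rep <- consistency(A)
  expect_equal(round(rep$cr, 3), 0.017)
  expect_equal(rep$ri, 0.90)

  expect_equal(unname(unclass(rank_to_matrix(c(2, 2, 2)))), matrix(1, 3, 3))

  A2 <- rank_to_matrix(c(1, 12))
  expect_equal(A2[2, 1], 9)
  expect_equal(A2[1, 2], 1/9)

  expect_error(rank_to_matrix(c(0, 1)), ">= 1")
  expect_error(rank_to_matrix(3), "two items")
})

test_that("values_to_matrix quantizes ratios, handles costs and zero dropouts", {
  expect_equal(unname(unclass(values_to_matrix(c(0.55, 0.55)))),
               matrix(1, 2, 2))

  # surface-tension example under the ceiling rule: ceil(45.0/34.6) = 2
  A <- values_to_matrix(c(34.6, 45.0), direction = -1, quantizer = "ceiling")
  expect_equal(A[1, 2], 2)
  expect_equal(A[2, 1], 1/2)

  # designed dropout: zero clear zone compares at maximal disparity
  Az <- values_to_matrix(c(6.5, 0.0))
  expect_equal(Az[1, 2], 9)
  Azz <- values_to_matrix(c(0, 0, 3))
  expect_equal(Azz[1, 2], 1)

  expect_error(values_to_matrix(c(-1, 2)), "nonnegative")
  expect_error(values_to_matrix(c(0, 0)), "all values are zero")
  expect_error(values_to_matrix(c(0, 2), direction = -1), "strictly positive")
})

test_that("value matrices satisfy reciprocity and Saaty quantization for every quantizer", {
  for (q in c("log", "ceiling", "nearest")) {
    for (seed in 1:5) {
      set.seed(seed)
      v <- runif(6, 0.1, 10)
      A <- values_to_matrix(v, quantizer = q)
      expect_saaty_valid(A)
      # benefit/cost symmetry: inverting values flips direction
      Ac <- values_to_matrix(1 / v, direction = -1, quantizer = q)
      expect_equal(unclass(A), unclass(Ac))
      # scale invariance
      As <- values_to_matrix(v * 37.5, quantizer = q)
      expect_equal(unclass(A), unclass(As))
    }
  }
})

test_that("screen tables validate structure and physical bounds", {
  df <- data.frame(label = c("a", "b"), biomass = c(0.5, 0.6),
                   protein = c(2, 3), surface_tension = c(40, 45),
                   clear_zone = c(5, 6))
  expect_s3_class(screen_table(df), "screen_table")
  expect_error(screen_table(df[1, ]), "at least 2")
  df2 <- df; df2$label <- c("a", "a")
  expect_error(screen_table(df2), "unique")
  df3 <- df; df3$surface_tension <- c(40, 140)
  expect_error(screen_table(df3), "\\(0, 100\\]")
  expect_error(screen_table(df[, -2]), "missing column")
})

test_that("run_screen is equivariant under row permutation and flags ties", {
  tab <- simulate_screen(noise_sd = 0.05, seed = 42)
  res <- run_screen(tab)
  perm <- c(3, 1, 5, 2, 4)
  tabp <- screen_table(tab$data[perm, ], criteria = tab$criteria)
  resp <- run_screen(tabp)
  expect_equal(unname(resp$hierarchy$overall),
               unname(res$hierarchy$overall)[perm], tolerance = 1e-12)
  expect_equal(resp$best_label, res$best_label)

  two <- screen_table(data.frame(
    label = c("a", "b"), biomass = c(0.5, 0.5), protein = c(2, 2),
    surface_tension = c(40, 40), clear_zone = c(5, 5)))
  expect_warning(res2 <- run_screen(two), "tie")
  expect_equal(unname(res2$hierarchy$overall), c(0.5, 0.5))
  expect_true(res2$hierarchy$tie)
})

test_that("a dominating alternative receives the highest overall weight", {
  dom <- screen_table(data.frame(
    label = c("best", "mid", "worst"),
    biomass = c(1.0, 0.6, 0.3), protein = c(6, 4, 2),
    surface_tension = c(31, 40, 50), clear_zone = c(7, 4, 2)))
  for (q in c("log", "ceiling", "nearest")) {
    expect_equal(run_screen(dom, quantizer = q)$best_label, "best")
  }
})

test_that("screen pipeline reproduces the published optima on the packaged tables", {
  cases <- list(
    c("temperature_screen.csv", "28"),
    c("nitrogen_source_screen.csv", "yeast_extract"),
    c("ion_screen.csv", "Na2HPO4"))
  for (cs in cases) {
    tab <- read_screen_csv(ahprsm_example(cs[1]))
    expect_equal(run_screen(tab)$best_label, cs[2], label = cs[1])
  }
  # temperature screen: every matrix passes the consistency test
  res <- run_screen(read_screen_csv(ahprsm_example("temperature_screen.csv")))
  expect_true(res$consistent)
  expect_true(all(res$footer$cr < 0.1))
})

test_that("composite response conserves mass and matches direct arithmetic", {
  x <- matrix(c(1, 2, 3, 4), ncol = 1)
  y <- composite_response(x, weights = 1, directions = 1)
  expect_equal(sum(y), 1)
  expect_equal(y, x[, 1] / sum(x))

  # all-equal indices give identical responses
  xe <- matrix(2, nrow = 4, ncol = 3)
  ye <- composite_response(xe, weights = c(0.2, 0.3, 0.5),
                           directions = c(1, 1, -1))
  expect_equal(diff(range(ye)), 0)

  # CCD sheet: signed column-sum normalization with the AHP criteria weights.
  # This reconstruction approximates the sheet's own response column (which
  # is used verbatim for fitting); frozen value from direct arithmetic.
  runs <- ccd_fixture()
  w <- priority_weights(criteria_matrix_4())
  Y <- composite_response(
    runs[, c("biomass", "protein_g_per_L", "surface_tension_mN_per_m",
             "clear_zone_cm")],
    weights = as.vector(w), directions = c(1, 1, -1, 1))
  expect_equal(round(Y[7], 4), -0.0116)
  expect_lt(max(abs(Y - runs$response)), 0.01)

  xz <- matrix(c(0, 0, 1, 2), ncol = 2)
  expect_error(composite_response(xz, weights = c(0.5, 0.5),
                                  directions = c(1, 1)),
               "zero column sum")
})
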