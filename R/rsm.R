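# canonical second-order term layout for k factors:
# intercept, k linear, k(k-1)/2 two-way interactions (i<j), k pure quadratics
quad_term_labels <- function(k) {
  lin <- paste0("x", seq_len(k))
  int <- character(0)
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      int <- c(int, paste0("x", i, ":x", j))
    }
  }
  c("(Intercept)", lin, int, paste0(lin, "^2"))
}

# n x p model matrix of the full quadratic in canonical term order
quad_model_matrix <- function(X) {
  k <- ncol(X)
  n <- nrow(X)
  cols <- list(rep(1, n))
  for (i in seq_len(k)) cols <- c(cols, list(X[, i]))
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cols <- c(cols, list(X[, i] * X[, j]))
    }
  }
  for (i in seq_len(k)) cols <- c(cols, list(X[, i]^2))
  M <- do.call(cbind, cols)
  colnames(M) <- quad_term_labels(k)
  M
}

#' Construct a second-order response-surface model from coefficients
#'
#' Low-level constructor wrapping a known coefficient vector (e.g. an
#' equation published in actual units) so it can be evaluated, optimized and
#' analyzed like a fitted model. Coefficient order: intercept, linear terms
#' `x1..xk`, two-way interactions `x1:x2, x1:x3, ..., x(k-1):xk`, pure
#' quadratics `x1^2..xk^2`.
#'
#' @param coefficients numeric vector of length `1 + 2k + k(k-1)/2`.
#' @param k number of factors.
#' @param coding `"coded"` or `"actual"`, a bookkeeping flag recording the
#'   unit system the coefficients live in.
#' @param mapping optional [factor_mapping()] linking the two unit systems.
#' @return object of class `"quadratic_model"`.
#' @export
quadratic_model <- function(coefficients, k, coding = c("coded", "actual"),
                            mapping = NULL) {
  coding <- match.arg(coding)
  p <- 1 + 2 * k + k * (k - 1) / 2
  if (length(coefficients) != p) {
    validation_error(sprintf(
      "expected %d coefficients for k = %d factors, got %d",
      p, k, length(coefficients)))
  }
  coefficients <- as.vector(coefficients)
  names(coefficients) <- quad_term_labels(k)
  structure(list(coefficients = coefficients, k = k, coding = coding,
                 mapping = mapping),
            class = "quadratic_model")
}

#' Fit the full second-order model to designed-experiment responses
#'
#' Ordinary least squares fit of the 10-term (for `k = 3`) quadratic
#' response surface: intercept, linear, two-way interaction and pure
#' quadratic terms. The fit goes through [stats::lm()] (QR decomposition);
#' residuals and leverages are retained for the PRESS statistic and the
#' lack-of-fit decomposition in [rsm_anova()].
#'
#' @param design coded run matrix (a [ccd_design()], or any matrix/data.frame
#'   whose `x1..xk` columns hold coded levels).
#' @param response numeric response vector, one value per run.
#' @param mapping optional [factor_mapping()] recorded on the model.
#' @return object of class `c("fitted_quadratic_model", "quadratic_model")`
#'   with elements `coefficients`, `fit` (the `lm` object), `design`,
#'   `response`, `residuals`, `fitted`, `hat`, `k`.
#' @examples
#' d <- ccd_design(3)
#' beta <- c(1, 0.5, -0.2, 0.1, 0, 0, 0, -0.3, -0.3, -0.3)
#' y <- predict(quadratic_model(beta, 3), d)
#' fit <- fit_quadratic(d, y)
#' max(abs(coef(fit) - beta)) < 1e-10
#' @export
fit_quadratic <- function(design, response, mapping = NULL) {
  X <- design_matrix(design)
  k <- ncol(X)
  n <- nrow(X)
  if (length(response) != n) {
    validation_error(sprintf("%d responses for %d runs", length(response), n))
  }
  p <- 1 + 2 * k + k * (k - 1) / 2
  if (n < p + 1) {
    validation_error(sprintf(
      "need more runs (%d) than the %d quadratic terms to estimate error", n, p))
  }
  M <- quad_model_matrix(X)
  qrM <- qr(M)
  if (qrM$rank < p) {
    bad <- colnames(M)[qrM$pivot[(qrM$rank + 1):p]]
    validation_error(paste("design is rank deficient; collinear column(s):",
                           paste(bad, collapse = ", ")))
  }
  dd <- as.data.frame(M[, -1, drop = FALSE])
  names(dd) <- paste0("t", seq_len(p - 1))       # syntactic stand-in names
  dd$.response <- response
  fit <- stats::lm(.response ~ ., data = dd)
  beta <- stats::coef(fit)
  names(beta) <- quad_term_labels(k)
  obj <- quadratic_model(beta, k, coding = "coded", mapping = mapping)
  obj$fit <- fit
  obj$design <- X
  obj$response <- response
  obj$residuals <- stats::resid(fit)
  obj$fitted <- stats::fitted(fit)
  obj$hat <- stats::hatvalues(fit)
  obj$model_matrix <- M
  class(obj) <- c("fitted_quadratic_model", class(obj))
  obj
}

#' @export
coef.quadratic_model <- function(object, ...) object$coefficients

#' @export
print.quadratic_model <- function(x, digits = 6, ...) {
  cat(sprintf("Second-order response-surface model (k = %d, %s units)%s\n",
              x$k, x$coding,
              if (inherits(x, "fitted_quadratic_model")) " [fitted]" else ""))
  print(signif(x$coefficients, digits))
  invisible(x)
}

#' Evaluate a quadratic response surface
#'
#' @param object a [quadratic_model()].
#' @param newdata matrix/data.frame of factor levels (columns = factors, in
#'   the unit system of the model), or a numeric vector for a single point.
#' @param ... unused.
#' @return numeric vector of predicted responses.
#' @export
predict.quadratic_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) {
    newdata <- matrix(as.numeric(newdata), nrow = 1)
  }
  X <- design_matrix(newdata)
  if (ncol(X) != object$k) {
    validation_error(sprintf("point dimension %d does not match k = %d",
                             ncol(X), object$k))
  }
  as.vector(quad_model_matrix(X) %*% object$coefficients)
}

#' ANOVA for a fitted response-surface model
#'
#' Variance decomposition of a [fit_quadratic()] fit in the style of DOE
#' software: the overall model row, a partial (drop-one) sum of squares row
#' per term, residual, lack-of-fit and pure-error rows, and the corrected
#' total. Pure error is the within-replicate-group sum of squares, with
#' replicate groups identified by exact coded-row equality (the center
#' replicates of a CCD); lack-of-fit rows are emitted only when replicates
#' exist. The fit statistics R2, adjusted R2 and predicted R2
#' (`1 - PRESS/SS_total`, PRESS from the leave-one-out hat-matrix closed
#' form) are attached as attributes.
#'
#' @param model a fitted quadratic model.
#' @return data.frame of class `"rsm_anova"` with columns `source`, `ss`,
#'   `df`, `ms`, `f`, `p` and attributes `r2`, `r2_adj`, `r2_pred`, `press`.
#' @export
rsm_anova <- function(model) {
  if (!inherits(model, "fitted_quadratic_model")) {
    validation_error("rsm_anova needs a model from fit_quadratic()")
  }
  y <- model$response
  n <- length(y)
  M <- model$model_matrix
  p <- ncol(M)
  e <- model$residuals
  ss_res <- sum(e^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- p - 1
  df_res <- n - p
  if (df_res < 1) validation_error("zero residual degrees of freedom")
  ms_res <- ss_res / df_res

  # partial (drop-one) SS for each single-df term: b_j^2 / [(X'X)^-1]_jj
  XtX_inv <- chol2inv(chol(crossprod(M)))
  b <- model$coefficients
  idx <- 2:p
  ss_term <- b[idx]^2 / diag(XtX_inv)[idx]
  f_term <- ss_term / ms_res
  p_term <- stats::pf(f_term, 1, df_res, lower.tail = FALSE)

  f_mod <- (ss_mod / df_mod) / ms_res
  p_mod <- stats::pf(f_mod, df_mod, df_res, lower.tail = FALSE)

  rows <- data.frame(
    source = c("Model", names(b)[idx]),
    ss = c(ss_mod, ss_term),
    df = c(df_mod, rep(1L, length(idx))),
    ms = c(ss_mod / df_mod, ss_term),
    f = c(f_mod, f_term),
    p = c(p_mod, p_term),
    stringsAsFactors = FALSE)

  # replicate groups (exact coded-row equality) -> pure error
  key <- apply(round(model$design, 10), 1, paste, collapse = "|")
  grp <- split(seq_len(n), key)
  reps <- grp[vapply(grp, length, 0L) > 1]
  ss_pe <- sum(vapply(reps, function(ix) sum((y[ix] - mean(y[ix]))^2), 0))
  df_pe <- sum(vapply(reps, length, 0L)) - length(reps)

  res_row <- data.frame(source = "Residual", ss = ss_res, df = df_res,
                        ms = ms_res, f = NA_real_, p = NA_real_)
  lof_rows <- NULL
  if (df_pe >= 1) {
    ss_lof <- ss_res - ss_pe
    df_lof <- df_res - df_pe
    f_lof <- if (df_lof >= 1) (ss_lof / df_lof) / (ss_pe / df_pe) else NA_real_
    p_lof <- if (df_lof >= 1) {
      stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    } else NA_real_
    lof_rows <- data.frame(
      source = c("Lack of fit", "Pure error"),
      ss = c(ss_lof, ss_pe), df = c(df_lof, df_pe),
      ms = c(if (df_lof >= 1) ss_lof / df_lof else NA_real_, ss_pe / df_pe),
      f = c(f_lof, NA_real_), p = c(p_lof, NA_real_))
  }
  tot_row <- data.frame(source = "Cor total", ss = ss_tot, df = n - 1,
                        ms = NA_real_, f = NA_real_, p = NA_real_)
  out <- rbind(rows, res_row, lof_rows, tot_row)
  rownames(out) <- NULL

  press <- sum((e / (1 - model$hat))^2)
  attr(out, "r2") <- 1 - ss_res / ss_tot
  attr(out, "r2_adj") <- 1 - ms_res / (ss_tot / (n - 1))
  attr(out, "r2_pred") <- 1 - press / ss_tot
  attr(out, "press") <- press
  class(out) <- c("rsm_anova", "data.frame")
  out
}

#' @export
print.rsm_anova <- function(x, ...) {
  cat("Response-surface ANOVA\n")
  df <- as.data.frame(x)
  df$ss <- signif(df$ss, 4)
  df$ms <- signif(df$ms, 4)
  df$f <- round(df$f, 2)
  df$p <- round(df$p, 4)
  print(df, row.names = FALSE, na.print = "")
  cat(sprintf("R2 = %.4f   adj R2 = %.4f   pred R2 = %.4f\n",
              attr(x, "r2"), attr(x, "r2_adj"), attr(x, "r2_pred")))
  invisible(x)
}

# split coefficients into intercept b0, gradient b (k), Hessian-half B (k x k)
# so that y = b0 + b'x + x'Bx with B_ii = beta_ii, B_ij = beta_ij / 2
quad_parts <- function(model) {
  k <- model$k
  co <- model$coefficients
  b0 <- co[1]
  b <- co[2:(k + 1)]
  B <- diag(co[(1 + k + k * (k - 1) / 2 + 1):length(co)], k)
  if (k >= 2) {
    pos <- k + 1
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pos <- pos + 1
      B[i, j] <- B[j, i] <- co[pos] / 2
    }
  }
  list(b0 = as.numeric(b0), b = as.numeric(b), B = B)
}

#' Stationary point of a quadratic response surface
#'
#' Solves `grad Y = 0` and classifies the stationary point through the
#' eigenvalue signs of the Hessian (all negative: maximum; all positive:
#' minimum; mixed: saddle). A partial assignment can freeze some factors at
#' fixed levels, in which case the system is solved on the free dimensions
#' only.
#'
#' @param model a [quadratic_model()].
#' @param frozen named numeric vector fixing a subset of factors (names
#'   `x1..xk`), or `NULL`.
#' @param tol singularity tolerance on the reciprocal condition number.
#' @return list with `point` (full-length, frozen values filled in),
#'   `value`, `classification` (`"maximum"`, `"minimum"`, `"saddle"`) and
#'   `hessian_eigenvalues`.
#' @export
stationary_point <- function(model, frozen = NULL, tol = 1e-10) {
  k <- model$k
  parts <- quad_parts(model)
  x <- rep(NA_real_, k)
  names(x) <- paste0("x", seq_len(k))
  free <- seq_len(k)
  if (!is.null(frozen)) {
    if (is.null(names(frozen)) || !all(names(frozen) %in% names(x))) {
      validation_error("frozen must be a named vector using factor names x1..xk")
    }
    fi <- match(names(frozen), names(x))
    x[fi] <- frozen
    free <- setdiff(free, fi)
  }
  if (length(free) == 0) {
    validation_error("all factors frozen; nothing to solve")
  }
  H <- 2 * parts$B[free, free, drop = FALSE]
  if (rcond(H) < tol) {
    validation_error("singular Hessian on the free dimensions; use constrained_optimum()")
  }
  rhs <- -(parts$b[free])
  if (length(free) < k) {
    rhs <- rhs - 2 * parts$B[free, -free, drop = FALSE] %*% x[-free]
  }
  x[free] <- solve(H, rhs)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  cls <- if (all(ev < 0)) "maximum" else if (all(ev > 0)) "minimum" else "saddle"
  list(point = x, value = predict(model, x),
       classification = cls, hessian_eigenvalues = ev)
}

#' Constrained optimum of a quadratic surface over a coded box
#'
#' Maximizes the predicted response over a box. If the unconstrained
#' stationary point is an interior maximum it is returned exactly; otherwise
#' a dense deterministic grid (default 101 points per axis) locates the
#' basin and a bounded quasi-Newton polish refines it.
#'
#' @param model a [quadratic_model()].
#' @param lower,upper box bounds per factor (recycled if scalar). Default
#'   the rotatable CCD region \[-1.682, 1.682\].
#' @param n_grid grid points per axis.
#' @return list with `point`, `value`, and `interior` (TRUE when the
#'   analytic stationary maximum lies inside the box).
#' @export
constrained_optimum <- function(model, lower = -1.682, upper = 1.682,
                                n_grid = 101) {
  k <- model$k
  lower <- rep_len(lower, k)
  upper <- rep_len(upper, k)
  if (any(lower >= upper)) validation_error("need lower < upper bounds")
  sp <- tryCatch(stationary_point(model), error = function(e) NULL)
  if (!is.null(sp) && sp$classification == "maximum" &&
      all(sp$point >= lower - 1e-12) && all(sp$point <= upper + 1e-12)) {
    return(list(point = pmin(pmax(sp$point, lower), upper),
                value = sp$value, interior = TRUE))
  }
  axes <- lapply(seq_len(k), function(i) seq(lower[i], upper[i], length.out = n_grid))
  grid <- as.matrix(do.call(expand.grid, axes))
  colnames(grid) <- paste0("x", seq_len(k))
  pred <- predict(model, grid)
  best <- grid[which.max(pred), ]
  opt <- stats::optim(best, function(z) -predict(model, z),
                      method = "L-BFGS-B", lower = lower, upper = upper)
  pt <- opt$par
  names(pt) <- paste0("x", seq_len(k))
  list(point = pt, value = -opt$value, interior = FALSE)
}

#' Estimate coding step sizes from a published actual-units equation
#'
#' When an experiment publishes its quadratic model in actual units but not
#' the coded-unit step sizes, the steps can be recovered from the pure
#' quadratic terms: a coded fit with step `s_i` satisfies
#' `beta_coded_ii = beta_actual_ii * s_i^2`, so
#' `s_i = sqrt(beta_coded_ii / beta_actual_ii)` whenever both curvatures are
#' nonzero and share a sign.
#'
#' @param coded_model fitted model in coded units.
#' @param actual_model [quadratic_model()] holding the actual-units equation.
#' @return numeric vector of step sizes (NA where a curvature is ~0).
#' @export
estimate_steps <- function(coded_model, actual_model) {
  k <- coded_model$k
  if (actual_model$k != k) validation_error("factor counts differ")
  qidx <- (1 + k + k * (k - 1) / 2 + 1):(1 + 2 * k + k * (k - 1) / 2)
  bc <- coded_model$coefficients[qidx]
  ba <- actual_model$coefficients[qidx]
  ratio <- bc / ba
  steps <- ifelse(is.finite(ratio) & ratio > 0 & abs(ba) > 1e-12,
                  sqrt(ratio), NA_real_)
  names(steps) <- paste0("x", seq_len(k))
  steps
}
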