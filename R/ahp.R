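#' Construct and validate a Saaty judgment matrix
#'
#' A judgment matrix `A = (a_ij)` holds pairwise ratio-scale comparisons of
#' `n` items: `a_ij` is the relative importance (or performance) of item `i`
#' over item `j`. A valid matrix has unit diagonal, is strictly positive, and
#' is reciprocal (`a_ji = 1/a_ij`).
#'
#' @param x numeric square matrix (or object coercible to one) of positive
#'   comparison values.
#' @param labels optional character vector of item names; defaults to existing
#'   row names or `item1..itemN`.
#' @param tol relative tolerance for the unit-diagonal and reciprocity checks.
#' @return a numeric matrix of class `"judgment_matrix"` with `labels` as
#'   dimnames.
#' @examples
#' judgment_matrix(rbind(c(1, 3), c(1/3, 1)), labels = c("a", "b"))
#' @seealso [priority_weights()], [consistency()]
#' @export
judgment_matrix <- function(x, labels = NULL, tol = 1e-9) {
  x <- as.matrix(x)
  if (!is.numeric(x)) {
    validation_error("judgment matrix must be numeric")
  }
  n <- nrow(x)
  if (n != ncol(x)) {
    validation_error(sprintf("judgment matrix must be square, got %d x %d",
                             n, ncol(x)))
  }
  if (n < 2) {
    validation_error("judgment matrix needs at least 2 items")
  }
  if (any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1, ]
    validation_error(sprintf("non-finite entry at [%d, %d]", bad[1], bad[2]))
  }
  if (any(x <= 0)) {
    bad <- which(x <= 0, arr.ind = TRUE)[1, ]
    validation_error(sprintf("entry [%d, %d] = %g is not strictly positive",
                             bad[1], bad[2], x[bad[1], bad[2]]))
  }
  if (any(abs(diag(x) - 1) > tol)) {
    i <- which(abs(diag(x) - 1) > tol)[1]
    validation_error(sprintf("diagonal entry [%d, %d] = %g must be 1",
                             i, i, x[i, i]))
  }
  rec <- abs(x * t(x) - 1) > tol
  if (any(rec)) {
    bad <- which(rec, arr.ind = TRUE)[1, ]
    validation_error(sprintf(
      "reciprocity violated at [%d, %d]: a_ij = %g but a_ji = %g (want 1/a_ij)",
      bad[1], bad[2], x[bad[1], bad[2]], x[bad[2], bad[1]]))
  }
  if (is.null(labels)) {
    labels <- rownames(x)
    if (is.null(labels)) labels <- paste0("item", seq_len(n))
  }
  if (length(labels) != n) {
    validation_error("labels length must equal matrix dimension")
  }
  dimnames(x) <- list(labels, labels)
  class(x) <- c("judgment_matrix", class(x))
  x
}

#' @export
print.judgment_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Judgment matrix (%d items)\n", nrow(x)))
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Saaty random consistency index
#'
#' The random index RI(n) is the expected consistency index of a random
#' reciprocal matrix of order `n`; it calibrates the consistency ratio
#' CR = CI/RI. Tabulated for n = 1..10.
#'
#' @param n matrix order, 1 to 10.
#' @param table optional replacement RI table (numeric, length 10, indexed by n).
#' @return the RI value for order `n`.
#' @export
random_index <- function(n, table = NULL) {
  ri <- if (is.null(table)) saaty_ri_table else table
  if (length(ri) < 10 || !is.numeric(ri)) {
    validation_error("RI table must be a numeric vector of length 10")
  }
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 1 || n > length(ri)) {
    validation_error(sprintf(
      "random index is tabulated for orders 1..%d only", length(ri)))
  }
  ri[[n]]
}

saaty_ri_table <- c(0.00, 0.00, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Priority weights of a judgment matrix
#'
#' Derives the priority (weight) vector of a judgment matrix. The default is
#' the geometric-mean (logarithmic least squares) method: each item's weight
#' is the geometric mean of its comparison row, normalized to sum 1. Geometric
#' means are computed in log space so extreme Saaty ratios cannot under- or
#' overflow. `method = "eigen"` returns the normalized principal (Perron)
#' eigenvector instead.
#'
#' @param matrix a [judgment_matrix()] (plain matrices are validated first).
#' @param method `"geometric"` (default) or `"eigen"`.
#' @return named numeric vector of weights summing to 1.
#' @examples
#' A <- judgment_matrix(rbind(c(1, 2), c(1/2, 1)))
#' priority_weights(A)
#' @export
priority_weights <- function(matrix, method = c("geometric", "eigen")) {
  method <- match.arg(method)
  A <- as_judgment(matrix)
  w <- switch(method,
    geometric = exp(rowMeans(log(unclass(A)))),
    eigen = {
      e <- eigen(unclass(A))
      v <- Re(e$vectors[, which.max(Re(e$values))])
      abs(v)
    })
  w <- w / sum(w)
  names(w) <- rownames(A)
  w
}

as_judgment <- function(x) {
  if (inherits(x, "judgment_matrix")) x else judgment_matrix(x)
}

#' Maximal eigenvalue estimate of a judgment matrix
#'
#' Estimates lambda_max, the principal eigenvalue of a positive reciprocal
#' matrix. The default `"row_ratio"` estimator averages the component-wise
#' ratios `(A w)_i / w_i` over the supplied priority vector, the classical
#' hand-calculation used in AHP worksheets. `"power"` runs power iteration to
#' the exact principal eigenvalue. For a perfectly consistent matrix both
#' equal `n`; inconsistency pushes lambda_max above `n`.
#'
#' @param matrix a [judgment_matrix()].
#' @param weights priority vector; defaults to geometric-mean weights.
#' @param method `"row_ratio"` (default) or `"power"`.
#' @param tol relative convergence tolerance for power iteration.
#' @param max_iter iteration cap for power iteration.
#' @return scalar lambda_max estimate.
#' @export
lambda_max <- function(matrix, weights = NULL,
                       method = c("row_ratio", "power"),
                       tol = 1e-10, max_iter = 10000L) {
  method <- match.arg(method)
  A <- as_judgment(matrix)
  n <- nrow(A)
  if (method == "power") {
    v <- rep(1 / n, n)
    lam <- n
    for (it in seq_len(max_iter)) {
      av <- as.vector(unclass(A) %*% v)
      lam_new <- sum(av * v) / sum(v * v)   # Rayleigh quotient
      av <- av / sum(av)
      if (abs(lam_new - lam) <= tol * abs(lam_new) && it > 1) {
        return(lam_new)
      }
      lam <- lam_new
      v <- av
    }
    return(lam)
  }
  if (is.null(weights)) weights <- priority_weights(A)
  if (length(weights) != n) {
    validation_error(sprintf(
      "weights length %d does not match matrix order %d", length(weights), n))
  }
  if (any(weights <= 0)) {
    validation_error("all weight components must be strictly positive")
  }
  mean(as.vector(unclass(A) %*% weights) / weights)
}

#' Consistency index CI
#'
#' `CI = (lambda_max - n) / (n - 1)`. Estimates of lambda_max marginally
#' below `n` (rounding artifacts) are clamped to `n`, so CI is never negative.
#'
#' @param lambda_max maximal eigenvalue estimate (`>= n` up to rounding).
#' @param n matrix order, `>= 2`.
#' @return scalar CI.
#' @examples
#' consistency_index(5.2623, 5)  # 0.0656 to 4 decimals
#' @export
consistency_index <- function(lambda_max, n) {
  if (!is.numeric(n) || length(n) != 1 || n != round(n) || n < 2) {
    validation_error("n must be an integer >= 2")
  }
  if (lambda_max < n - 1e-6) {
    validation_error(sprintf(
      "lambda_max = %g below matrix order n = %d: not a reciprocal-matrix eigenvalue",
      lambda_max, n))
  }
  max(lambda_max - n, 0) / (n - 1)
}

#' Consistency ratio CR and verdict
#'
#' `CR = CI / RI(n)`; judgments are conventionally accepted when `CR < 0.1`.
#' Matrices of order 1 or 2 are always consistent (RI = 0 there, so CR is
#' defined as 0 rather than divided out).
#'
#' @param ci consistency index, `>= 0`.
#' @param n matrix order (2..10; the RI table domain).
#' @param ri_table optional replacement RI table passed to [random_index()].
#' @param cr_threshold acceptance threshold on CR (default 0.1).
#' @return an object of class `"consistency_report"`: a list with
#'   `lambda_max`, `ci`, `ri`, `cr`, `acceptable`, `n`.
#' @examples
#' consistency_ratio(consistency_index(5.2623, 5), 5)  # CR 0.0585
#' @export
consistency_ratio <- function(ci, n, ri_table = NULL, cr_threshold = 0.1) {
  if (!is.numeric(ci) || length(ci) != 1 || ci < 0) {
    validation_error("ci must be a single nonnegative number")
  }
  ri <- random_index(n, table = ri_table)
  cr <- if (n <= 2) 0 else ci / ri
  structure(
    list(lambda_max = ci * (n - 1) + n, ci = if (n <= 2) 0 else ci,
         ri = ri, cr = cr, acceptable = cr < cr_threshold,
         n = as.integer(n), cr_threshold = cr_threshold),
    class = "consistency_report")
}

#' Full consistency diagnostics for a judgment matrix
#'
#' Convenience chain: priority weights, lambda_max, CI, CR and the
#' accept/reject verdict for one matrix.
#'
#' @param matrix a [judgment_matrix()].
#' @param weights_method prioritization method, see [priority_weights()].
#' @param lambda_method lambda_max estimator, see [lambda_max()].
#' @inheritParams consistency_ratio
#' @return a `"consistency_report"` (see [consistency_ratio()]) with the
#'   priority vector attached as attribute `"weights"`.
#' @examples
#' A <- judgment_matrix(rbind(c(1, 1/2, 1/3, 1/4), c(2, 1, 1/2, 1/2),
#'                            c(3, 2, 1, 1/2),    c(4, 2, 2, 1)))
#' consistency(A)
#' @export
consistency <- function(matrix, weights_method = "geometric",
                        lambda_method = "row_ratio",
                        ri_table = NULL, cr_threshold = 0.1) {
  A <- as_judgment(matrix)
  n <- nrow(A)
  w <- priority_weights(A, method = weights_method)
  lam <- lambda_max(A, weights = w, method = lambda_method)
  ci <- consistency_index(lam, n)
  rep <- consistency_ratio(ci, n, ri_table = ri_table,
                           cr_threshold = cr_threshold)
  rep$lambda_max <- lam
  attr(rep, "weights") <- w
  rep
}

#' @export
print.consistency_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Consistency report (n = %d): lambda_max = %s, CI = %s, RI = %s, CR = %s [%s]\n",
    x$n, format(round(x$lambda_max, digits)), format(round(x$ci, digits)),
    format(round(x$ri, digits)), format(round(x$cr, digits)),
    if (x$acceptable) sprintf("acceptable, CR < %g", x$cr_threshold)
    else sprintf("INCONSISTENT, CR >= %g", x$cr_threshold)))
  invisible(x)
}

#' Serialize a consistency report to JSON
#'
#' @param report a `"consistency_report"`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
consistency_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "consistency_report"))
  obj <- report[c("lambda_max", "ci", "ri", "cr", "acceptable")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Hierarchical synthesis of criterion and alternative priorities
#'
#' Combines criterion-level weights with one alternative-level priority vector
#' per criterion into overall alternative priorities:
#' `overall_j = sum_c criteria[c] * per_criterion[[c]][j]`. The alternative
#' with the highest overall priority is selected; exact ties break to the
#' earliest alternative with a warning, and the tie is recorded.
#'
#' @param criteria numeric vector of criterion weights (must sum to 1 within
#'   1e-6; normalized exactly internally).
#' @param per_criterion list of alternative priority vectors, one per
#'   criterion, sharing one label set.
#' @return an object of class `"hierarchy_result"`: list with
#'   `criteria_weights`, `alternative_weights` (alternatives x criteria
#'   matrix), `overall`, `best_index`, `best_label`, `tie`.
#' @export
ahp_synthesize <- function(criteria, per_criterion) {
  if (!is.list(per_criterion) || length(per_criterion) == 0) {
    validation_error("per_criterion must be a non-empty list of priority vectors")
  }
  m <- length(per_criterion)
  if (length(criteria) != m) {
    validation_error(sprintf(
      "%d criteria weights supplied for %d alternative vectors", length(criteria), m))
  }
  if (any(criteria < 0) || abs(sum(criteria) - 1) > 1e-6) {
    validation_error("criteria weights must be nonnegative and sum to 1")
  }
  criteria <- criteria / sum(criteria)
  labs <- names(per_criterion[[1]])
  k <- length(per_criterion[[1]])
  W <- matrix(NA_real_, nrow = k, ncol = m)
  for (c in seq_len(m)) {
    v <- per_criterion[[c]]
    if (length(v) != k) {
      validation_error("alternative priority vectors differ in length")
    }
    if (!is.null(labs) && !is.null(names(v)) && !identical(names(v), labs)) {
      validation_error(sprintf(
        "alternative labels of criterion %d do not match the first criterion", c))
    }
    W[, c] <- v
  }
  if (is.null(labs)) labs <- paste0("alt", seq_len(k))
  dimnames(W) <- list(labs, names(per_criterion))
  overall <- as.vector(W %*% criteria)
  names(overall) <- labs
  top <- max(overall)
  winners <- which(abs(overall - top) <= 1e-12)
  tie <- length(winners) > 1
  if (tie) {
    warning(sprintf("tie for best alternative among: %s; keeping the first",
                    paste(labs[winners], collapse = ", ")))
  }
  structure(
    list(criteria_weights = criteria, alternative_weights = W,
         overall = overall, best_index = unname(winners[1]),
         best_label = labs[winners[1]], tie = tie),
    class = "hierarchy_result")
}

#' @export
print.hierarchy_result <- function(x, digits = 4, ...) {
  cat("AHP hierarchy synthesis\n")
  df <- data.frame(round(x$alternative_weights, digits),
                   overall = round(x$overall, digits),
                   check.names = FALSE)
  print(df)
  cat(sprintf("Best alternative: %s (overall weight %s)%s\n", x$best_label,
              format(round(x$overall[x$best_index], digits)),
              if (x$tie) " [tie broken to earliest]" else ""))
  invisible(x)
}
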