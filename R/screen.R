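#' Default criteria for biosurfactant screening experiments
#'
#' The four production indices used to score culture conditions, with their
#' optimization direction and importance rank. Surface tension is the one
#' cost criterion (lower is better, direction -1); biomass, protein and
#' clear-zone diameter are benefits (+1). Importance increases with rank:
#' biomass 1, protein 2, surface tension 3, clear-zone diameter 4, i.e. the
#' clear zone is weighted heaviest and biomass lightest.
#'
#' @return data.frame with columns `criterion`, `direction`, `rank`.
#' @export
default_criteria <- function() {
  data.frame(
    criterion = c("biomass", "protein", "surface_tension", "clear_zone"),
    direction = c(1, 1, -1, 1),
    rank = c(1L, 2L, 3L, 4L),
    stringsAsFactors = FALSE)
}

validate_criteria <- function(criteria) {
  need <- c("criterion", "direction", "rank")
  if (!is.data.frame(criteria) || !all(need %in% names(criteria))) {
    validation_error("criteria must be a data.frame with columns criterion, direction, rank")
  }
  if (!all(criteria$direction %in% c(-1, 1))) {
    validation_error("criterion direction must be +1 (benefit) or -1 (cost)")
  }
  if (any(criteria$rank < 1) || any(criteria$rank != round(criteria$rank))) {
    validation_error("criterion ranks must be positive integers")
  }
  criteria
}

#' Judgment matrix from importance ranks
#'
#' Reconstructs a Saaty comparison matrix from integer importance scores:
#' for scores `s_i >= s_j` the comparison is `a_ij = ceiling(s_i / s_j)`
#' clipped to the Saaty range \[1, 9\], with `a_ji = 1 / a_ij`. With scores
#' (1, 2, 3, 4) this yields the criteria matrix whose geometric-mean weights
#' round to (0.10, 0.18, 0.29, 0.43) with CR 0.017.
#'
#' @param ranks positive integer importance scores, higher = more important.
#' @param labels optional item names.
#' @return a [judgment_matrix()].
#' @examples
#' rank_to_matrix(c(1, 2, 3, 4))
#' @export
rank_to_matrix <- function(ranks, labels = NULL) {
  if (length(ranks) < 2 || any(!is.finite(ranks)) || any(ranks < 1)) {
    validation_error("ranks must be >= 1 and at least two items long")
  }
  n <- length(ranks)
  A <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        hi <- max(ranks[i], ranks[j]); lo <- min(ranks[i], ranks[j])
        a <- min(9, ceiling(hi / lo - 1e-9))
        if (ranks[i] >= ranks[j]) {
          A[i, j] <- a; A[j, i] <- 1 / a
        } else {
          A[i, j] <- 1 / a; A[j, i] <- a
        }
      }
    }
  }
  judgment_matrix(A, labels = labels)
}

#' Saaty-scale quantizers for measured-value ratios
#'
#' Maps a performance ratio `r >= 1` onto the discrete Saaty scale 1..9.
#' Three rules are provided:
#' * `"log"` (default): `round(1 + 8 * log(r) / log(9))`, a logarithmic map
#'   that places a 9-fold advantage at intensity 9 and grades smaller
#'   advantages geometrically;
#' * `"ceiling"`: `ceiling(r)` clipped to 9 (the rule that reproduces the
#'   rank-based criteria matrix);
#' * `"nearest"`: `round(r)` clipped to \[1, 9\].
#'
#' @param type one of `"log"`, `"ceiling"`, `"nearest"`, or a function
#'   `ratio -> integer in 1..9` for a custom rule.
#' @return a vectorized quantizer function.
#' @export
saaty_quantizer <- function(type = c("log", "ceiling", "nearest")) {
  if (is.function(type)) return(type)
  type <- match.arg(type)
  switch(type,
    log = function(r) pmin(9, pmax(1, round(1 + 8 * log(r) / log(9)))),
    ceiling = function(r) pmin(9, ceiling(r - 1e-9)),
    nearest = function(r) pmin(9, pmax(1, round(r))))
}

#' Judgment matrix from measured index values
#'
#' Converts one column of screen measurements into a pairwise comparison
#' matrix. Cost criteria (`direction = -1`, e.g. surface tension) are
#' inverted first, so a lower measurement compares as better. The ratio of
#' effective values is quantized onto the Saaty scale (see
#' [saaty_quantizer()]). Zero effective values encode designed dropouts
#' (e.g. no clear zone): any positive-vs-zero comparison is the maximal
#' intensity 9, zero-vs-zero is 1.
#'
#' @param values numeric measurements, `>= 0` (strictly positive for cost
#'   criteria).
#' @param direction `+1` (benefit) or `-1` (cost).
#' @param quantizer quantizer name or function, see [saaty_quantizer()].
#' @param labels optional item names.
#' @return a [judgment_matrix()].
#' @examples
#' values_to_matrix(c(34.6, 45.0), direction = -1, quantizer = "ceiling")
#' @export
values_to_matrix <- function(values, direction = 1, quantizer = "log",
                             labels = NULL) {
  if (length(values) < 2) {
    validation_error("need at least two values to compare")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    validation_error("values must be finite and nonnegative")
  }
  if (all(values == 0)) {
    validation_error("all values are zero; nothing to compare")
  }
  if (direction < 0 && any(values <= 0)) {
    validation_error("cost criteria require strictly positive values")
  }
  q <- saaty_quantizer(quantizer)
  v <- if (direction < 0) 1 / values else values
  n <- length(v)
  A <- matrix(1, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        a <- if (v[i] == 0 && v[j] == 0) 1
             else if (v[j] == 0) 9
             else if (v[i] == 0) 1 / 9
             else if (v[i] >= v[j]) q(v[i] / v[j])
             else 1 / q(v[j] / v[i])
        A[i, j] <- a; A[j, i] <- 1 / a
      }
    }
  }
  judgment_matrix(A, labels = labels)
}

#' Assemble a single-factor screen table
#'
#' One screening experiment: alternatives (temperature levels, carbon
#' sources, ...) in rows, the four production indices in columns.
#'
#' @param data data.frame with columns `label`, `biomass` (OD600), `protein`
#'   (g/L), `surface_tension` (mN/m), `clear_zone` (cm). The long CSV-dialect
#'   names `protein_g_per_L`, `surface_tension_mN_per_m`, `clear_zone_cm` are
#'   also accepted.
#' @param experiment experiment name used in reports.
#' @param criteria criteria specification, see [default_criteria()].
#' @return an object of class `"screen_table"`.
#' @export
screen_table <- function(data, experiment = "screen",
                         criteria = default_criteria()) {
  data <- as.data.frame(data)
  long <- c(protein_g_per_L = "protein",
            surface_tension_mN_per_m = "surface_tension",
            clear_zone_cm = "clear_zone")
  for (nm in names(long)) {
    if (nm %in% names(data) && !(long[[nm]] %in% names(data))) {
      names(data)[names(data) == nm] <- long[[nm]]
    }
  }
  criteria <- validate_criteria(criteria)
  need <- c("label", criteria$criterion)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    validation_error(paste("screen table missing column(s):",
                           paste(miss, collapse = ", ")))
  }
  if (nrow(data) < 2) {
    validation_error("screen table needs at least 2 alternatives")
  }
  data$label <- as.character(data$label)
  if (anyDuplicated(data$label)) {
    validation_error("alternative labels must be unique")
  }
  for (cc in criteria$criterion) {
    col <- data[[cc]]
    if (!is.numeric(col) || any(!is.finite(col)) || any(col < 0)) {
      validation_error(sprintf("column '%s' must be finite and nonnegative", cc))
    }
  }
  if ("surface_tension" %in% criteria$criterion) {
    st <- data$surface_tension
    if (any(st <= 0 | st > 100)) {
      validation_error("surface tension must lie in (0, 100] mN/m")
    }
  }
  structure(list(data = data[, need], experiment = experiment,
                 criteria = criteria),
            class = "screen_table")
}

#' @export
print.screen_table <- function(x, ...) {
  cat(sprintf("Screen table '%s': %d alternatives x %d criteria\n",
              x$experiment, nrow(x$data), nrow(x$criteria)))
  print(x$data, row.names = FALSE)
  invisible(x)
}

#' Run the AHP screening pipeline on one screen table
#'
#' Builds the criteria judgment matrix from the importance ranks
#' ([rank_to_matrix()]), one alternative judgment matrix per criterion from
#' the measured values ([values_to_matrix()]), checks every matrix for
#' consistency, synthesizes overall alternative weights and selects the best
#' alternative. When any matrix has `CR >= cr_threshold` the result carries a
#' non-fatal inconsistency flag (`consistent = FALSE`).
#'
#' @param table a [screen_table()].
#' @param quantizer quantizer for value matrices, see [saaty_quantizer()].
#' @param lambda_method lambda_max estimator, see [lambda_max()].
#' @param cr_threshold CR acceptance threshold.
#' @return an object of class `"screen_result"`: list with `criteria_report`,
#'   `criteria_weights`, `reports` (per-criterion consistency reports),
#'   `hierarchy` ([ahp_synthesize()] result), `consistent`, `best_label`,
#'   and `report`, a data.frame echoing the screen-table layout with the
#'   overall weight column appended.
#' @examples
#' tab <- read_screen_csv(ahprsm_example("temperature_screen.csv"),
#'                        experiment = "temperature")
#' res <- run_screen(tab)
#' res$best_label
#' @export
run_screen <- function(table, quantizer = "log", lambda_method = "row_ratio",
                       cr_threshold = 0.1) {
  if (!inherits(table, "screen_table")) {
    validation_error("run_screen expects a screen_table")
  }
  crit <- table$criteria
  labs <- table$data$label
  crit_mat <- rank_to_matrix(crit$rank, labels = crit$criterion)
  crit_rep <- consistency(crit_mat, lambda_method = lambda_method,
                          cr_threshold = cr_threshold)
  crit_w <- attr(crit_rep, "weights")
  reports <- list()
  alt_w <- list()
  for (i in seq_len(nrow(crit))) {
    cc <- crit$criterion[i]
    A <- values_to_matrix(table$data[[cc]], direction = crit$direction[i],
                          quantizer = quantizer, labels = labs)
    rep <- consistency(A, lambda_method = lambda_method,
                       cr_threshold = cr_threshold)
    reports[[cc]] <- rep
    alt_w[[cc]] <- attr(rep, "weights")
  }
  hier <- ahp_synthesize(as.vector(crit_w), alt_w)
  consistent <- crit_rep$acceptable && all(vapply(reports, `[[`, TRUE, "acceptable"))
  report <- cbind(table$data,
                  overall_weight = as.vector(hier$overall))
  footer <- data.frame(
    criterion = names(reports),
    lambda_max = vapply(reports, `[[`, 0, "lambda_max"),
    ci = vapply(reports, `[[`, 0, "ci"),
    ri = vapply(reports, `[[`, 0, "ri"),
    cr = vapply(reports, `[[`, 0, "cr"),
    acceptable = vapply(reports, `[[`, TRUE, "acceptable"),
    row.names = NULL)
  structure(
    list(experiment = table$experiment, criteria = crit,
         criteria_matrix = crit_mat, criteria_report = crit_rep,
         criteria_weights = crit_w, reports = reports, hierarchy = hier,
         consistent = consistent, best_label = hier$best_label,
         best_index = hier$best_index, report = report, footer = footer),
    class = "screen_result")
}

#' @export
print.screen_result <- function(x, digits = 4, ...) {
  cat(sprintf("AHP screen '%s'\n", x$experiment))
  rep <- x$report
  rep$overall_weight <- round(rep$overall_weight, digits)
  print(rep, row.names = FALSE)
  cat("\nPer-criterion consistency:\n")
  f <- x$footer
  f[, c("lambda_max", "ci", "ri", "cr")] <-
    round(f[, c("lambda_max", "ci", "ri", "cr")], digits)
  print(f, row.names = FALSE)
  cat(sprintf("Criteria matrix: "))
  print(x$criteria_report, digits = digits)
  cat(sprintf("Best alternative: %s%s\n", x$best_label,
              if (!x$consistent) "  [WARNING: some CR >= threshold]" else ""))
  invisible(x)
}

#' Composite response from the four indices
#'
#' Collapses the index measurements of a set of runs into a single response
#' per run: each index column is normalized across runs, signed by its
#' optimization direction, and combined with the AHP criteria weights:
#' `Y_k = sum_c w_c * sign_c * x_ck / N_c` where `N_c` is the column
#' normalizer. Normalizations: `"colsum"` (default, column sum), `"max"`
#' (column maximum), `"minmax"` (range-scaled). With a single benefit
#' criterion and colsum normalization the responses sum to 1.
#'
#' @param indices matrix or data.frame, runs x criteria, column order
#'   matching `weights`/`directions`.
#' @param weights criteria weights (summing to 1).
#' @param directions vector of +1/-1 per criterion.
#' @param normalization `"colsum"`, `"max"` or `"minmax"`.
#' @return numeric vector of composite responses, one per run.
#' @export
composite_response <- function(indices, weights, directions,
                               normalization = c("colsum", "max", "minmax")) {
  normalization <- match.arg(normalization)
  X <- as.matrix(indices)
  if (nrow(X) < 2) validation_error("need at least 2 runs")
  m <- ncol(X)
  if (length(weights) != m || length(directions) != m) {
    validation_error("weights and directions must match the number of index columns")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-6) {
    validation_error("criteria weights must be nonnegative and sum to 1")
  }
  Z <- switch(normalization,
    colsum = {
      cs <- colSums(X)
      if (any(cs == 0 & directions > 0)) {
        validation_error("zero column sum for a benefit criterion under colsum normalization")
      }
      sweep(X, 2, ifelse(cs == 0, 1, cs), "/")
    },
    max = {
      cm <- apply(X, 2, max)
      sweep(X, 2, ifelse(cm == 0, 1, cm), "/")
    },
    minmax = {
      lo <- apply(X, 2, min); hi <- apply(X, 2, max)
      rng <- ifelse(hi > lo, hi - lo, 1)
      sweep(sweep(X, 2, lo, "-"), 2, rng, "/")
    })
  as.vector(Z %*% (weights * directions))
}
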