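#' Generate a central composite design
#'
#' Builds the coded design matrix of a CCD: the `2^k` factorial points at
#' +/-1, `2k` axial (star) points at +/-`alpha` on one axis each, and
#' `n_center` replicated center points. The canonical run order is factorial
#' block (standard order), axial block (factor by factor, low then high),
#' then centers; `shuffle = TRUE` applies a seeded random run order.
#' `alpha = (2^k)^(1/4)` gives the rotatable design; for `k = 3` that is
#' 1.682, the five coded levels being -1.682, -1, 0, +1, +1.682.
#'
#' @param k number of factors, `>= 2`.
#' @param alpha axial distance in coded units (default rotatable).
#' @param n_center number of center replicates.
#' @param shuffle randomize the run order.
#' @param seed seed used when `shuffle = TRUE`.
#' @return object of class `"ccd_design"`: data.frame with columns `run`,
#'   `x1..xk` and `role` (`"factorial"`, `"axial"`, `"center"`).
#' @examples
#' d <- ccd_design(3, alpha = 1.682, n_center = 6)
#' nrow(d)  # 20 runs
#' @export
ccd_design <- function(k = 3, alpha = (2^k)^0.25, n_center = 6,
                       shuffle = FALSE, seed = NULL) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k) || k < 2) {
    validation_error("k must be an integer >= 2")
  }
  if (alpha <= 0) validation_error("alpha must be positive")
  if (n_center < 1 || n_center != round(n_center)) {
    validation_error("n_center must be a positive integer")
  }
  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2 * k, ncol = k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -alpha
    axial[2 * i, i] <- alpha
  }
  center <- matrix(0, nrow = n_center, ncol = k)
  X <- rbind(fact, axial, center)
  colnames(X) <- paste0("x", seq_len(k))
  role <- c(rep("factorial", nrow(fact)), rep("axial", nrow(axial)),
            rep("center", n_center))
  ord <- seq_len(nrow(X))
  if (shuffle) {
    if (!is.null(seed)) set.seed(seed)
    ord <- sample(ord)
  }
  out <- data.frame(run = seq_len(nrow(X)), X[ord, , drop = FALSE],
                    role = role[ord], row.names = NULL)
  attr(out, "k") <- k
  attr(out, "alpha") <- alpha
  attr(out, "n_center") <- as.integer(n_center)
  class(out) <- c("ccd_design", "data.frame")
  out
}

#' Coded/actual factor mapping
#'
#' Linear coding of factor levels: `coded = (actual - center) / step`. The
#' default mapping carries the medium-composition factors lactose (center
#' 5 g/L), yeast extract (6 g/L) and NaCl (20 g/L); step sizes (g/L per coded
#' unit) must be supplied by the experimental protocol.
#'
#' @param name factor names.
#' @param center actual-unit values at coded 0.
#' @param step actual units per coded unit, `> 0`.
#' @return data.frame of class `"factor_mapping"`.
#' @export
factor_mapping <- function(name, center, step) {
  if (length(name) != length(center) || length(name) != length(step)) {
    validation_error("name, center and step must have equal length")
  }
  if (any(step <= 0)) validation_error("step sizes must be positive")
  structure(data.frame(name = as.character(name), center = center, step = step,
                       stringsAsFactors = FALSE),
            class = c("factor_mapping", "data.frame"))
}

#' @rdname factor_mapping
#' @param actual matrix/data.frame of actual-unit levels (columns = factors).
#' @param mapping a [factor_mapping()].
#' @export
code_values <- function(actual, mapping) {
  X <- as.matrix(actual)
  if (ncol(X) != nrow(mapping)) {
    validation_error("column count does not match the factor mapping")
  }
  sweep(sweep(X, 2, mapping$center, "-"), 2, mapping$step, "/")
}

#' @rdname factor_mapping
#' @param coded matrix/data.frame of coded levels.
#' @export
decode_values <- function(coded, mapping) {
  X <- as.matrix(coded)
  if (ncol(X) != nrow(mapping)) {
    validation_error("column count does not match the factor mapping")
  }
  sweep(sweep(X, 2, mapping$step, "*"), 2, mapping$center, "+")
}

# extract the coded factor columns x1..xk from a design object
design_matrix <- function(design) {
  if (inherits(design, "ccd_design")) {
    k <- attr(design, "k")
    X <- as.matrix(design[, paste0("x", seq_len(k)), drop = FALSE])
  } else {
    X <- as.matrix(design)
    xcols <- grep("^x[0-9]+$", colnames(X))
    if (length(xcols)) X <- X[, xcols, drop = FALSE]
  }
  storage.mode(X) <- "double"
  X
}
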