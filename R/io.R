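# CSV dialect everywhere: UTF-8, comma separator, "." decimal, header required

#' Path to a packaged example data file
#'
#' The package ships the transcribed screening tables and the 20-run CCD
#' sheet of a marine *Vibrio* biosurfactant medium-optimization experiment
#' as plain-CSV fixtures, plus the default criteria configuration.
#'
#' @param file file name inside `extdata`; with no argument, lists the
#'   available files.
#' @return full path (or a character vector of file names).
#' @examples
#' ahprsm_example()
#' @export
ahprsm_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "ahprsm")))
  }
  path <- system.file("extdata", file, package = "ahprsm")
  if (path == "") validation_error(sprintf("no packaged file '%s'", file))
  path
}

#' Read / write a judgment matrix as square CSV
#'
#' The on-disk form is a square table with a header row and a leading label
#' column, mirroring the matrix layout.
#'
#' @param path file path.
#' @return [read_judgment_csv()] returns a [judgment_matrix()].
#' @export
read_judgment_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) validation_error("judgment CSV needs a label column and >= 2 items")
  labs <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  judgment_matrix(M, labels = labs)
}

#' @rdname read_judgment_csv
#' @param matrix a [judgment_matrix()].
#' @export
write_judgment_csv <- function(matrix, path) {
  A <- as_judgment(matrix)
  df <- data.frame(label = rownames(A), unclass(A), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write screen tables as CSV
#'
#' Columns: `label,biomass,protein_g_per_L,surface_tension_mN_per_m,clear_zone_cm`
#' (short names `protein`, `surface_tension`, `clear_zone` are also accepted
#' on input).
#'
#' @param path file path.
#' @param experiment experiment name for the resulting table.
#' @param criteria criteria specification, see [default_criteria()].
#' @return a [screen_table()].
#' @export
read_screen_csv <- function(path, experiment = basename(path),
                            criteria = default_criteria()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) validation_error(sprintf("empty screen table: %s", path))
  screen_table(df, experiment = experiment, criteria = criteria)
}

#' @rdname read_screen_csv
#' @param table a [screen_table()].
#' @export
write_screen_csv <- function(table, path) {
  stopifnot(inherits(table, "screen_table"))
  df <- table$data
  names(df) <- c("label", "biomass", "protein_g_per_L",
                 "surface_tension_mN_per_m", "clear_zone_cm")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write CCD run sheets as CSV
#'
#' Minimal columns `run,x1..xk,response` (coded levels); extra columns such
#' as measured index values are preserved.
#'
#' @param path file path.
#' @return data.frame with at least the coded factor columns; the `response`
#'   column, when present, is numeric.
#' @export
read_ccd_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
  if (length(xcols) < 2) {
    validation_error("CCD CSV needs coded factor columns x1, x2, ...")
  }
  for (cc in c(xcols, intersect("response", names(df)))) {
    if (!is.numeric(df[[cc]])) {
      validation_error(sprintf("column '%s' must be numeric", cc))
    }
  }
  df
}

#' @rdname read_ccd_csv
#' @param runs data.frame of runs (e.g. a [ccd_design()] with a response
#'   column bound on).
#' @export
write_ccd_csv <- function(runs, path) {
  utils::write.csv(as.data.frame(runs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a quadratic model as JSON
#'
#' Full-precision round trip: coefficients are written with `digits = NA`,
#' so a reloaded model reproduces stored predictions exactly.
#'
#' @param model a [quadratic_model()].
#' @param path file path.
#' @return [read_model_json()] returns a [quadratic_model()].
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "quadratic_model"))
  obj <- list(k = model$k, coding = model$coding,
              coefficients = as.list(model$coefficients))
  if (!is.null(model$mapping)) {
    obj$mapping <- as.data.frame(model$mapping)
  }
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path)
  mapping <- if (!is.null(obj$mapping)) {
    factor_mapping(obj$mapping$name, obj$mapping$center, obj$mapping$step)
  }
  quadratic_model(unlist(obj$coefficients), k = obj$k, coding = obj$coding,
                  mapping = mapping)
}

#' Load and validate a pipeline configuration file
#'
#' YAML configuration covering the tunable choices of the pipeline. Allowed
#' keys: `criteria` (list of `name`/`direction`/`rank`), `quantizer`,
#' `lambda_method`, `cr_threshold`, `normalization`, `factors` (list of
#' `name`/`center`/`step`), `bounds` (`lower`/`upper`), `seed`, `out_dir`.
#' Unknown keys are rejected before any computation.
#'
#' @param path YAML file path.
#' @return validated named list with class `"pipeline_config"`; absent keys
#'   are filled with package defaults.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  allowed <- c("criteria", "quantizer", "lambda_method", "cr_threshold",
               "normalization", "factors", "bounds", "seed", "out_dir")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    validation_error(paste("unknown configuration key(s):",
                           paste(unknown, collapse = ", ")))
  }
  defaults <- list(quantizer = "log", lambda_method = "row_ratio",
                   cr_threshold = 0.1, normalization = "colsum",
                   criteria = default_criteria(), factors = NULL,
                   bounds = list(lower = -1.682, upper = 1.682),
                   seed = NULL, out_dir = ".")
  if (!is.null(cfg$criteria)) {
    cr <- do.call(rbind, lapply(cfg$criteria, function(x) {
      if (!all(c("name", "direction", "rank") %in% names(x))) {
        validation_error("each criteria entry needs name, direction, rank")
      }
      data.frame(criterion = x$name, direction = x$direction, rank = x$rank,
                 stringsAsFactors = FALSE)
    }))
    cfg$criteria <- validate_criteria(cr)
  }
  if (!is.null(cfg$quantizer) &&
      !cfg$quantizer %in% c("log", "ceiling", "nearest")) {
    validation_error("quantizer must be one of: log, ceiling, nearest")
  }
  if (!is.null(cfg$lambda_method) &&
      !cfg$lambda_method %in% c("row_ratio", "power")) {
    validation_error("lambda_method must be row_ratio or power")
  }
  if (!is.null(cfg$cr_threshold) &&
      (!is.numeric(cfg$cr_threshold) || cfg$cr_threshold <= 0)) {
    validation_error("cr_threshold must be a positive number")
  }
  if (!is.null(cfg$normalization) &&
      !cfg$normalization %in% c("colsum", "max", "minmax")) {
    validation_error("normalization must be colsum, max or minmax")
  }
  if (!is.null(cfg$factors)) {
    fm <- do.call(rbind, lapply(cfg$factors, function(x) {
      if (!all(c("name", "center", "step") %in% names(x))) {
        validation_error("each factors entry needs name, center, step")
      }
      data.frame(name = x$name, center = x$center, step = x$step,
                 stringsAsFactors = FALSE)
    }))
    cfg$factors <- factor_mapping(fm$name, fm$center, fm$step)
  }
  out <- utils::modifyList(defaults, cfg)
  class(out) <- "pipeline_config"
  out
}

#' Render a screen result as aligned text
#'
#' @param result a [run_screen()] result.
#' @param digits display rounding (machine-readable outputs keep full
#'   precision).
#' @return character vector of report lines.
#' @export
format_screen_report <- function(result, digits = 4) {
  stopifnot(inherits(result, "screen_result"))
  utils::capture.output(print(result, digits = digits))
}

#' Render an ANOVA table as aligned text
#'
#' @param anova_table an [rsm_anova()] table.
#' @return character vector of report lines.
#' @export
format_anova <- function(anova_table) {
  stopifnot(inherits(anova_table, "rsm_anova"))
  utils::capture.output(print(anova_table))
}
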