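#' Read and validate an annual climate CSV
#'
#' Expects a header row and at least `year`, `T` and `P` columns; optional
#' envelope columns `T_min`, `T_max`, `P_min`, `P_max`. Every row is
#' validated (numeric cells, `P >= 0`, envelopes bracketing the central
#' values); offending rows are reported by line number in a single error.
#'
#' @param path CSV path.
#' @param col_names Optional named character vector remapping file columns
#'   to the canonical names, e.g. `c(T = "temp_c", P = "precip_mm")`.
#' @return Validated data.frame of climate years.
#' @export
read_climate_csv <- function(path, col_names = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, check.names = FALSE)
  if (!is.null(col_names)) {
    for (canon in names(col_names)) {
      src <- col_names[[canon]]
      if (!src %in% names(x)) {
        stop("column '", src, "' not found in ", path, call. = FALSE)
      }
      names(x)[names(x) == src] <- canon
    }
  }
  need <- c("year", "T", "P")
  missing_col <- setdiff(need, names(x))
  if (length(missing_col)) {
    stop("climate CSV is missing required columns: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  numcols <- intersect(c("year", "T", "P", "T_min", "T_max", "P_min", "P_max"),
                       names(x))
  bad <- integer(0)
  for (col in numcols) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- union(bad, which(is.na(v)))
    x[[col]] <- v
  }
  if (length(bad)) {
    stop("non-numeric or missing cells in row(s) ",
         paste(sort(bad), collapse = ", "), " of ", path, call. = FALSE)
  }
  problems <- character(0)
  chk <- function(cond, msg) {
    rows <- which(cond)
    if (length(rows)) {
      problems <<- c(problems, paste0(msg, " in row(s) ",
                                      paste(rows, collapse = ", ")))
    }
  }
  chk(x$P < 0, "negative precipitation")
  if (all(c("T_min", "T_max") %in% names(x))) {
    chk(!(x$T_min <= x$T & x$T <= x$T_max), "T outside [T_min, T_max]")
  }
  if (all(c("P_min", "P_max") %in% names(x))) {
    chk(!(x$P_min <= x$P & x$P <= x$P_max), "P outside [P_min, P_max]")
  }
  if (length(problems)) {
    stop(paste(problems, collapse = "; "), call. = FALSE)
  }
  x
}

#' Read an occurrence-climate CSV
#'
#' Expects `id`, `lon`, `lat`, `T_base`, `P_base` plus at least one matched
#' pair of `T_2070_<abbr>` / `P_2070_<abbr>` model columns.
#'
#' @param path CSV path.
#' @return Validated data.frame in the occurrence dialect.
#' @export
read_occurrence_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, check.names = FALSE)
  need <- c("id", "lon", "lat", "T_base", "P_base")
  missing_col <- setdiff(need, names(x))
  if (length(missing_col)) {
    stop("occurrence CSV is missing required columns: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  labels <- occ_model_labels(x)   # errors on unpaired T/P columns
  if (!length(labels)) {
    stop("occurrence CSV has no model projection columns (T_2070_*)",
         call. = FALSE)
  }
  x
}

#' Read a reproductive-status record CSV
#'
#' Per-individual dialect (`year`, `status`, `T`, `P`) or grouped dialect
#' (`year`, `successes`, `trials`, `T`, `P`).
#'
#' @param path CSV path.
#' @return Validated data.frame suitable for [fit_fertility_model()].
#' @export
read_repro_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, check.names = FALSE)
  grouped <- all(c("successes", "trials") %in% names(x))
  need <- c("year", "T", "P", if (grouped) c("successes", "trials") else "status")
  missing_col <- setdiff(need, names(x))
  if (length(missing_col)) {
    stop("record CSV is missing required columns: ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  }
  if (!grouped && !all(x$status %in% c(0, 1))) {
    stop("status must be binary (0/1) in ", path, call. = FALSE)
  }
  x
}

#' Write a table as CSV (no row names)
#'
#' @param x Data frame.
#' @param path Output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Assemble a multi-scenario summary report
#'
#' One row per simulation in input order with the conventional summary
#' columns (Mean, % Change, Minimum, Maximum, Standard Deviation).
#'
#' @param results List of `simulation_result` objects (>= 1).
#' @return Data.frame of class `simulation_report` with columns `scenario`,
#'   `rcp`, `mean`, `pct_change`, `min`, `max`, `sd`.
#' @export
report <- function(results) {
  if (inherits(results, "simulation_result")) results <- list(results)
  if (!length(results)) stop("no simulation results to report", call. = FALSE)
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "simulation_result"))
    cbind(data.frame(scenario = r$scenario_name, rcp = r$rcp), r$summary)
  })
  structure(do.call(rbind, rows),
            class = c("simulation_report", "data.frame"))
}

#' Format a report in the conventional printed style
#'
#' Populations as rounded integers, percent change signed with two
#' decimals (e.g. `+3.50`).
#'
#' @param x A [report()] data.frame.
#' @return Character data.frame ready for printing or CSV emission.
#' @export
format_report <- function(x) {
  stopifnot(inherits(x, "simulation_report"))
  data.frame(
    scenario = x$scenario,
    mean = sprintf("%.0f", x$mean),
    pct_change = sprintf("%+.2f", x$pct_change),
    min = sprintf("%.0f", x$min),
    max = sprintf("%.0f", x$max),
    sd = sprintf("%.0f", x$sd)
  )
}

#' @export
print.simulation_report <- function(x, ...) {
  f <- format_report(x)
  names(f) <- c("Scenario", "Mean", "% Change", "Minimum", "Maximum", "SD")
  print(f, row.names = FALSE)
  invisible(x)
}

#' Build a run manifest
#'
#' Records what produced a result file: inputs, scenario, seed, package
#' version, timestamp, and any row-exclusion counts. Pair every emitted
#' result with one of these via [write_manifest()].
#'
#' @param inputs Named character vector or list of input paths/identifiers.
#' @param scenario Scenario name.
#' @param rcp RCP label.
#' @param seed Root seed used.
#' @param excluded Named list/vector of row-exclusion counts (default none).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(inputs = list(), scenario = NA_character_,
                         rcp = NA_character_, seed = NA_integer_,
                         excluded = list()) {
  structure(list(
    inputs = inputs, scenario = scenario, rcp = rcp, seed = seed,
    package_version = as.character(utils::packageVersion("batpva")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    excluded = excluded
  ), class = "run_manifest")
}

#' Write a run manifest as JSON next to its result file
#'
#' @param manifest A [run_manifest()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
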