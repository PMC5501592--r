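#' Construct a scenario specification
#'
#' A scenario is a per-year adult-fertility driver: for every simulated year
#' a central fertility with a (min, max) envelope used for environmental
#' stochasticity. Normally built via [stable_scenario()],
#' [yearly_series_scenario()] or [step_scenario()].
#'
#' @param years Integer vector of calendar years (consecutive).
#' @param fertility Central adult fertility per year.
#' @param fmin,fmax Per-year envelope bounds (min <= central <= max).
#' @param name Scenario name.
#' @param rcp RCP tag (`"stable"`, `"RCP2.6"`, `"RCP4.5"`, `"RCP6.0"`,
#'   `"RCP8.5"`).
#' @param mode One of `"constant"`, `"yearly_series"`, `"step_ramp"`.
#' @param baseline Baseline adult fertility the scenario is anchored to.
#' @return A data.frame (`year`, `fertility`, `fmin`, `fmax`) of class
#'   `scenario_spec` with attributes `name`, `rcp`, `mode`, `baseline`.
#' @export
scenario_spec <- function(years, fertility, fmin = fertility, fmax = fertility,
                          name = "scenario", rcp = "stable",
                          mode = c("constant", "yearly_series", "step_ramp"),
                          baseline = fertility[1]) {
  mode <- match.arg(mode)
  n <- length(years)
  stopifnot(n >= 1, length(fertility) == n, length(fmin) == n,
            length(fmax) == n)
  if (any(diff(years) != 1)) {
    stop("years must be consecutive calendar years", call. = FALSE)
  }
  bad <- which(!(fmin <= fertility + 1e-12 & fertility <= fmax + 1e-12))
  if (length(bad)) {
    stop("envelope violated (need min <= central <= max) in year(s) ",
         paste(years[bad], collapse = ", "), call. = FALSE)
  }
  if (any(fmin < 0)) stop("fertility envelope must be non-negative",
                          call. = FALSE)
  structure(
    data.frame(year = as.integer(years), fertility = fertility,
               fmin = fmin, fmax = fmax),
    class = c("scenario_spec", "data.frame"),
    name = name, rcp = rcp, mode = mode, baseline = baseline
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s, %s): years %d-%d, fertility %.3f -> %.3f\n",
              attr(x, "name"), attr(x, "rcp"), attr(x, "mode"),
              min(x$year), max(x$year),
              x$fertility[1], x$fertility[nrow(x)]))
  invisible(x)
}

#' Stable-conditions scenario
#'
#' Adult fertility held at the baseline rate for every simulated year, with
#' the standard environmental envelope (0.9, 1.1) x central.
#'
#' @param rates A [vital_rates()] object supplying the baseline adult
#'   fertility.
#' @param years Simulated calendar years (default 2009--2086, 77 years).
#' @param env_multipliers Envelope multipliers (default `c(0.9, 1.1)`).
#' @return A [scenario_spec()].
#' @export
stable_scenario <- function(rates, years = 2009:2086,
                            env_multipliers = c(0.9, 1.1)) {
  stopifnot(inherits(rates, "vital_rates"))
  f <- rep(rates$adult_fertility, length(years))
  scenario_spec(years, f, env_multipliers[1] * f, env_multipliers[2] * f,
                name = "Stable Population", rcp = "stable",
                mode = "constant", baseline = rates$adult_fertility)
}

#' Yearly-series scenario from a projected climate series
#'
#' Predicts the central adult fertility from each year's (T, P) and the
#' envelope from the extremes of the four corner combinations of
#' (T_min | T_max) x (P_min | P_max). With the default coefficient signs
#' (betaT < 0, betaP > 0) the minimum lies at (T_max, P_min) and the maximum
#' at (T_min, P_max), but corners are evaluated explicitly so any
#' coefficient signs are handled.
#'
#' @param coefficients [logistic_coefficients()].
#' @param climate Data frame with columns `year`, `T`, `P` and optionally
#'   `T_min`, `T_max`, `P_min`, `P_max` (absent ranges collapse to the
#'   central values).
#' @param years Years the scenario must cover (default 2009--2086); missing
#'   years raise an error listing the gaps.
#' @param name,rcp Labels stored on the scenario.
#' @return A [scenario_spec()].
#' @export
yearly_series_scenario <- function(coefficients, climate, years = 2009:2086,
                                   name = "yearly series", rcp = "RCP4.5") {
  stopifnot(is.data.frame(climate))
  need <- c("year", "T", "P")
  missing_col <- setdiff(need, names(climate))
  if (length(missing_col)) {
    stop("climate is missing columns: ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  gaps <- setdiff(years, climate$year)
  if (length(gaps)) {
    stop("climate series is missing years: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  }
  cl <- climate[match(years, climate$year), ]
  for (col in c("T_min", "T_max")) if (is.null(cl[[col]])) cl[[col]] <- cl$T
  for (col in c("P_min", "P_max")) if (is.null(cl[[col]])) cl[[col]] <- cl$P

  central <- predict_fertility(coefficients, cl$T, cl$P)
  corners <- cbind(
    predict_fertility(coefficients, cl$T_min, cl$P_min),
    predict_fertility(coefficients, cl$T_min, cl$P_max),
    predict_fertility(coefficients, cl$T_max, cl$P_min),
    predict_fertility(coefficients, cl$T_max, cl$P_max)
  )
  fmin <- pmin(apply(corners, 1, min), central)
  fmax <- pmax(apply(corners, 1, max), central)
  scenario_spec(years, central, fmin, fmax, name = name, rcp = rcp,
                mode = "yearly_series", baseline = central[1])
}

#' Step-ramp scenario to a 2070 endpoint
#'
#' Linear fertility ramp: each year carries an equal increment
#' `delta = (endpoint - baseline) / (endpoint_year - (start_year - 1))`, so
#' the central value hits the endpoint exactly in `endpoint_year` and
#' continues past it at the same slope through the final year. Central
#' values are floored at 0; the envelope is (0.9, 1.1) x central.
#'
#' @param baseline_fertility Adult fertility in the year before the series
#'   starts (in (0, 1\]).
#' @param endpoint_fertility Adult fertility reached in `endpoint_year`
#'   (in (0, 1\]).
#' @param years Simulated calendar years (default 2009--2086).
#' @param endpoint_year Year the ramp is anchored to (default 2070; must lie
#'   inside `years`).
#' @param env_multipliers Envelope multipliers (default `c(0.9, 1.1)`).
#' @param name,rcp Labels stored on the scenario.
#' @return A [scenario_spec()].
#' @examples
#' s <- step_scenario(0.85, 0.70)
#' s$fertility[s$year == 2070]   # exactly 0.70
#' @export
step_scenario <- function(baseline_fertility, endpoint_fertility,
                          years = 2009:2086, endpoint_year = 2070,
                          env_multipliers = c(0.9, 1.1),
                          name = "step ramp", rcp = "RCP4.5") {
  for (v in c(baseline_fertility, endpoint_fertility)) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0 || v > 1) {
      stop("baseline and endpoint fertility must lie in (0, 1]", call. = FALSE)
    }
  }
  if (endpoint_year < min(years) || endpoint_year > max(years)) {
    stop("endpoint_year ", endpoint_year, " lies outside the simulated years ",
         min(years), "-", max(years), call. = FALSE)
  }
  anchor <- min(years) - 1L
  delta <- (endpoint_fertility - baseline_fertility) / (endpoint_year - anchor)
  central <- pmax(baseline_fertility + (years - anchor) * delta, 0)
  scenario_spec(years, central,
                env_multipliers[1] * central, env_multipliers[2] * central,
                name = name, rcp = rcp, mode = "step_ramp",
                baseline = baseline_fertility)
}

occ_model_labels <- function(occ) {
  tcols <- grep("^T_2070_", names(occ), value = TRUE)
  if (!length(tcols)) return(character(0))
  labels <- sub("^T_2070_", "", tcols)
  pcols <- paste0("P_2070_", labels)
  missing_p <- pcols[!(pcols %in% names(occ))]
  if (length(missing_p)) {
    stop("occurrence table is missing precipitation columns: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  labels
}

#' Grand ensemble mean 2070 fertility over occurrence locations
#'
#' Predicts year-2070 fertility at every (location, climate model) pair,
#' averages over models within each location, then averages over locations.
#' With a complete table this equals the flat grand mean over all pairs.
#' Missing model entries (NA) are excluded; the excluded count is reported
#' via `message()` and attached as attribute `"n_excluded"`.
#'
#' @param coefficients [logistic_coefficients()].
#' @param occurrence Data frame in the occurrence-climate dialect: columns
#'   `id`, `lon`, `lat`, `T_base`, `P_base`, and per-model pairs
#'   `T_2070_<abbr>` / `P_2070_<abbr>`.
#' @param rcp_label RCP tag carried through to the result attribute.
#' @return Scalar grand-mean 2070 fertility, with attributes `rcp` and
#'   `n_excluded`.
#' @export
ensemble_endpoint <- function(coefficients, occurrence, rcp_label = "RCP4.5") {
  stopifnot(is.data.frame(occurrence))
  if (nrow(occurrence) == 0) stop("empty occurrence table", call. = FALSE)
  labels <- occ_model_labels(occurrence)
  if (!length(labels)) {
    stop("occurrence table has no model projection columns (T_2070_*)",
         call. = FALSE)
  }
  preds <- sapply(labels, function(lb) {
    Tm <- occurrence[[paste0("T_2070_", lb)]]
    Pm <- occurrence[[paste0("P_2070_", lb)]]
    ifelse(is.na(Tm) | is.na(Pm), NA_real_,
           predict_fertility(coefficients,
                             ifelse(is.na(Tm), 0, Tm),
                             ifelse(is.na(Pm), 0, Pm)))
  })
  preds <- matrix(preds, nrow = nrow(occurrence))
  n_excluded <- sum(is.na(preds))
  if (n_excluded > 0) {
    message(n_excluded, " missing (location, model) entries excluded")
  }
  loc_means <- rowMeans(preds, na.rm = TRUE)
  if (any(!is.finite(loc_means))) {
    stop("some locations have no model projections at all", call. = FALSE)
  }
  structure(mean(loc_means), rcp = rcp_label, n_excluded = n_excluded)
}

#' Per-location fertility change table
#'
#' For each occurrence location, the change in predicted adult fertility
#' between the baseline climate and the mean of the per-model year-2070
#' projections: `delta_i = projected_i - baseline_i`. The grand means
#' (mean projected fertility and mean change over locations) are attached
#' as attributes `f_bar` and `delta_bar`.
#'
#' @inheritParams ensemble_endpoint
#' @return Data frame with columns `id`, `lon`, `lat`, `baseline_fertility`,
#'   `projected_fertility`, `delta`; attributes `f_bar`, `delta_bar`, `rcp`.
#' @export
fertility_change_table <- function(coefficients, occurrence,
                                   rcp_label = "RCP4.5") {
  stopifnot(is.data.frame(occurrence))
  if (nrow(occurrence) == 0) stop("empty occurrence table", call. = FALSE)
  labels <- occ_model_labels(occurrence)
  base <- predict_fertility(coefficients, occurrence$T_base, occurrence$P_base)
  preds <- sapply(labels, function(lb) {
    Tm <- occurrence[[paste0("T_2070_", lb)]]
    Pm <- occurrence[[paste0("P_2070_", lb)]]
    ifelse(is.na(Tm) | is.na(Pm), NA_real_,
           predict_fertility(coefficients,
                             ifelse(is.na(Tm), 0, Tm),
                             ifelse(is.na(Pm), 0, Pm)))
  })
  preds <- matrix(preds, nrow = nrow(occurrence))
  projected <- rowMeans(preds, na.rm = TRUE)
  out <- data.frame(
    id = occurrence$id,
    lon = occurrence$lon,
    lat = occurrence$lat,
    baseline_fertility = base,
    projected_fertility = projected,
    delta = projected - base
  )
  structure(out,
            f_bar = mean(projected),
            delta_bar = mean(out$delta),
            rcp = rcp_label)
}
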