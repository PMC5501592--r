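#' Specification for the synthetic data generators
#'
#' Controls the three generators that emulate the pipeline's external
#' inputs: a yearly climate table (annual mean temperature and
#' precipitation with min/max envelopes), per-individual reproductive-status
#' records driven by a known logistic model, and an occurrence-climate table
#' with per-model year-2070 projections.
#'
#' Defaults mirror the reference study system: a 13-year capture series
#' (1996--2008) of roughly 15 adult females per year (about 190 records), a
#' Boulder-like baseline climate (10.85 deg C, 541 mm), the packaged
#' logistic coefficients as truth, and eleven CMIP5-style climate models
#' whose 2070 offsets straddle a mid-range warming of about +2.7 deg C with
#' little systematic precipitation change.
#'
#' @param seed Root seed; each generator derives a fixed child offset so the
#'   three outputs are mutually independent yet jointly reproducible.
#' @param years Calendar years of the capture series.
#' @param records_per_year Adult females evaluated per year.
#' @param beta True logistic coefficients (beta0, betaT, betaP).
#' @param T0,P0 Climate at the first year (deg C, mm).
#' @param T_trend,P_trend Linear trend per year (deg C/yr, mm/yr).
#' @param T_jitter,P_jitter Interannual Gaussian jitter SDs.
#' @param T_halfwidth,P_halfwidth Half-widths of the min/max envelope
#'   columns around the central value.
#' @param n_locations Occurrence locations to generate.
#' @param base_T_sd,base_P_sd Across-location SD of baseline climate.
#' @param model_labels Climate-model abbreviations (up to 11).
#' @param model_dT,model_dP Named per-model 2070 offsets (deg C, mm).
#' @param proj_jitter SD of location-level jitter added to each model's 2070
#'   projection (applied to temperature; scaled x50 for precipitation).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 42L,
                           years = 1996:2008,
                           records_per_year = 15L,
                           beta = c(2.6419, -0.2534, 0.0040),
                           T0 = 10.85, P0 = 541,
                           T_trend = 0, P_trend = 0,
                           T_jitter = 0.6, P_jitter = 60,
                           T_halfwidth = 1.0, P_halfwidth = 80,
                           n_locations = 200L,
                           base_T_sd = 2.5, base_P_sd = 120,
                           model_labels = c("BC", "CC", "GS", "HD", "HE",
                                            "IP", "MC", "MI", "MR", "MG",
                                            "NO"),
                           model_dT = NULL, model_dP = NULL,
                           proj_jitter = 0.2) {
  if (records_per_year < 1) stop("records_per_year must be >= 1", call. = FALSE)
  if (n_locations < 1) stop("n_locations must be >= 1", call. = FALSE)
  if (any(c(T_jitter, P_jitter, proj_jitter) < 0)) {
    stop("jitter SDs must be >= 0", call. = FALSE)
  }
  if (length(beta) != 3 || any(!is.finite(beta))) {
    stop("beta must be three finite coefficients", call. = FALSE)
  }
  if (is.null(model_dT)) {
    # spread of 2070 warming across models, centred near +2.7 deg C
    model_dT <- seq(1.6, 3.8, length.out = length(model_labels))
  }
  if (is.null(model_dP)) {
    # no systematic drying; models disagree mildly on precipitation
    model_dP <- seq(-30, 30, length.out = length(model_labels))
  }
  names(model_dT) <- names(model_dP) <- model_labels
  structure(list(seed = as.integer(seed), years = as.integer(years),
                 records_per_year = as.integer(records_per_year),
                 beta = beta, T0 = T0, P0 = P0,
                 T_trend = T_trend, P_trend = P_trend,
                 T_jitter = T_jitter, P_jitter = P_jitter,
                 T_halfwidth = T_halfwidth, P_halfwidth = P_halfwidth,
                 n_locations = as.integer(n_locations),
                 base_T_sd = base_T_sd, base_P_sd = base_P_sd,
                 model_labels = model_labels,
                 model_dT = model_dT, model_dP = model_dP,
                 proj_jitter = proj_jitter),
            class = "synthetic_spec")
}

#' Generate a trending annual climate series
#'
#' `T(y) = T0 + T_trend * (y - y0) + N(0, T_jitter)`, and likewise for
#' precipitation (floored at 0); min/max columns are central -/+ the stated
#' half-widths. Pure function of (spec, years): the same inputs always give
#' the identical table.
#'
#' @param spec A [synthetic_spec()].
#' @param years Years to generate (default `spec$years`).
#' @return Data frame with columns `year`, `T`, `P`, `T_min`, `T_max`,
#'   `P_min`, `P_max`.
#' @export
gen_climate_series <- function(spec, years = spec$years) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- length(years)
  dy <- years - years[1]
  Tc <- spec$T0 + spec$T_trend * dy + stats::rnorm(n, 0, spec$T_jitter)
  Pc <- pmax(spec$P0 + spec$P_trend * dy + stats::rnorm(n, 0, spec$P_jitter), 0)
  data.frame(year = as.integer(years), T = Tc, P = Pc,
             T_min = Tc - spec$T_halfwidth, T_max = Tc + spec$T_halfwidth,
             P_min = pmax(Pc - spec$P_halfwidth, 0),
             P_max = Pc + spec$P_halfwidth)
}

#' Generate reproductive-status records under the known logistic model
#'
#' For each year, `records_per_year` adult females each with status ~
#' Bernoulli(plogis(beta0 + betaT * T_y + betaP * P_y)) at that year's
#' climate.
#'
#' @param spec A [synthetic_spec()].
#' @param climate Climate series covering the requested years (default: the
#'   spec's own [gen_climate_series()]).
#' @param years Years to generate records for (default `spec$years`).
#' @return Data frame with columns `year`, `status`, `T`, `P` — the
#'   record-table dialect read by [fit_fertility_model()].
#' @export
gen_repro_records <- function(spec, climate = gen_climate_series(spec),
                              years = spec$years) {
  stopifnot(inherits(spec, "synthetic_spec"))
  gaps <- setdiff(years, climate$year)
  if (length(gaps)) {
    stop("climate series is missing years: ", paste(gaps, collapse = ", "),
         call. = FALSE)
  }
  set.seed(spec$seed + 1L)
  cl <- climate[match(years, climate$year), ]
  p_year <- predict_fertility(spec$beta, cl$T, cl$P)
  n <- spec$records_per_year
  out <- do.call(rbind, lapply(seq_along(years), function(i) {
    data.frame(year = as.integer(years[i]),
               status = stats::rbinom(n, 1, p_year[i]),
               T = cl$T[i], P = cl$P[i])
  }))
  rownames(out) <- NULL
  out
}

#' Generate an occurrence-climate table
#'
#' Baseline climates are drawn around the spec's means with across-location
#' spread; each climate model's year-2070 projection is baseline + the
#' model's offset + location-level jitter. Longitudes/latitudes are drawn
#' uniformly over a western-North-America bounding box (they are carried
#' through but never used in computation).
#'
#' @param spec A [synthetic_spec()].
#' @return Data frame in the occurrence dialect: `id`, `lon`, `lat`,
#'   `T_base`, `P_base`, then `T_2070_<abbr>` / `P_2070_<abbr>` per model.
#' @export
gen_occurrence_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 2L)
  n <- spec$n_locations
  out <- data.frame(
    id = seq_len(n),
    lon = stats::runif(n, -125, -102),
    lat = stats::runif(n, 31, 49),
    T_base = stats::rnorm(n, spec$T0, spec$base_T_sd),
    P_base = pmax(stats::rnorm(n, spec$P0, spec$base_P_sd), 0)
  )
  for (lb in spec$model_labels) {
    out[[paste0("T_2070_", lb)]] <-
      out$T_base + spec$model_dT[[lb]] + stats::rnorm(n, 0, spec$proj_jitter)
    out[[paste0("P_2070_", lb)]] <-
      pmax(out$P_base + spec$model_dP[[lb]] +
             stats::rnorm(n, 0, 50 * spec$proj_jitter), 0)
  }
  out
}
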