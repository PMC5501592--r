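#' Triangular distribution specification
#'
#' @param minimum,mode,maximum Triangle parameters (minimum <= mode <=
#'   maximum). Degenerate triangles (all equal) are allowed and sample the
#'   mode exactly.
#' @return A list of class `triangular_spec`.
#' @export
triangular_spec <- function(minimum, mode, maximum) {
  if (!(is.finite(minimum) && is.finite(mode) && is.finite(maximum))) {
    stop("triangular parameters must be finite", call. = FALSE)
  }
  if (minimum > mode || mode > maximum) {
    stop(sprintf("need minimum <= mode <= maximum (got %g, %g, %g)",
                 minimum, mode, maximum), call. = FALSE)
  }
  structure(list(minimum = minimum, mode = mode, maximum = maximum),
            class = "triangular_spec")
}

#' Triangular quantile function (inverse CDF)
#'
#' Vectorised over `p` and the parameters. Used both for sampling (with
#' uniform variates) and for closed-form checks.
#'
#' @param p Probabilities in \[0, 1\].
#' @param minimum,mode,maximum Triangle parameters.
#' @return Quantiles in \[minimum, maximum\].
#' @export
qtriangular <- function(p, minimum, mode, maximum) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(p), length(minimum), length(mode), length(maximum))
  p <- rep_len(p, n)
  a <- rep_len(minimum, n)
  m <- rep_len(mode, n)
  b <- rep_len(maximum, n)
  if (any(a > m | m > b)) {
    stop("need minimum <= mode <= maximum", call. = FALSE)
  }
  w <- b - a
  out <- m                      # degenerate triangles sample the mode exactly
  pos <- w > 0
  Fm <- numeric(n)
  Fm[pos] <- (m[pos] - a[pos]) / w[pos]
  left <- pos & p <= Fm
  right <- pos & p > Fm
  out[left] <- a[left] + sqrt(p[left] * w[left] * (m[left] - a[left]))
  out[right] <- b[right] - sqrt((1 - p[right]) * w[right] * (b[right] - m[right]))
  pmin(pmax(out, a), b)
}

#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling from the current R random stream.
#'
#' @param spec A [triangular_spec()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` within the triangle's support.
#' @examples
#' set.seed(1)
#' mean(draw_triangular(triangular_spec(0.9, 1.0, 1.1), 1e4))
#' @export
draw_triangular <- function(spec, n = 1) {
  stopifnot(inherits(spec, "triangular_spec"))
  qtriangular(stats::runif(n), spec$minimum, spec$mode, spec$maximum)
}

#' Monte Carlo simulation configuration
#'
#' @param scenario A [scenario_spec()] supplying the per-year adult-fertility
#'   central values and environmental envelope.
#' @param rates A [vital_rates()] object.
#' @param initial Length-4 initial female class vector (default
#'   `c(600, 290, 230, 880)`, 2,000 females near the stable distribution).
#' @param n_runs Number of replicates (default 10,000).
#' @param n_years Annual transitions per replicate (default 77, or the
#'   scenario length if shorter). The scenario table carries one fertility
#'   row per calendar year 2009--2086; a replicate starting from the 2009
#'   census reaches the 2086 census after 77 transitions, consuming the
#'   fertility of years 2009--2085 (births at the end of year y are censused
#'   on day 1 of year y + 1).
#' @param halfwidth Demographic-noise half-width as a fraction of the rate
#'   (default 0.10, i.e. triangles on (0.9, 1.0, 1.1) x rate).
#' @param seed Root RNG seed; every replicate derives its own child stream,
#'   so results are reproducible and replicate-parallelisable.
#' @param demographic Toggle demographic (per-rate) stochasticity.
#' @param environmental Toggle environmental (fertility-envelope)
#'   stochasticity.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(scenario, rates = vital_rates(),
                              initial = c(600, 290, 230, 880),
                              n_runs = 10000L,
                              n_years = min(nrow(scenario), 77L),
                              halfwidth = 0.10, seed = 1L,
                              demographic = TRUE, environmental = TRUE) {
  stopifnot(inherits(scenario, "scenario_spec"), inherits(rates, "vital_rates"))
  if (length(initial) != 4 || any(initial < 0)) {
    stop("initial must be 4 non-negative class counts", call. = FALSE)
  }
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  if (n_years < 0 || n_years > nrow(scenario)) {
    stop("n_years must lie in [0, scenario length]", call. = FALSE)
  }
  if (halfwidth < 0) stop("halfwidth must be >= 0", call. = FALSE)
  structure(list(scenario = scenario, rates = rates, initial = initial,
                 n_runs = as.integer(n_runs), n_years = as.integer(n_years),
                 halfwidth = halfwidth, seed = as.integer(seed),
                 demographic = isTRUE(demographic),
                 environmental = isTRUE(environmental)),
            class = "simulation_config")
}

# Per-class fertility triple for one year: the scenario's adult central and
# envelope, scaled per class (pups 0, yearlings x yearling_factor). When
# environmental noise is off the envelope collapses to the central value;
# when demographic noise is on but no environmental envelope is in force the
# fertility triangle is the +/- halfwidth one. Environmental and demographic
# fertility noise are never stacked: the scenario envelope already spans the
# year's plausible range.
fertility_triple <- function(central, fmin, fmax, config) {
  if (config$environmental) {
    lo <- fmin; hi <- fmax
  } else if (config$demographic) {
    lo <- (1 - config$halfwidth) * central
    hi <- (1 + config$halfwidth) * central
  } else {
    lo <- central; hi <- central
  }
  list(lo = lo, mid = central, hi = hi)
}

survival_triple <- function(s, config) {
  if (config$demographic) {
    list(lo = (1 - config$halfwidth) * s, mid = s,
         hi = pmin((1 + config$halfwidth) * s, 1))
  } else {
    list(lo = s, mid = s, hi = s)
  }
}

# class multipliers applied to the adult fertility driver
class_fertility_multipliers <- function(rates) {
  c(0, rates$yearling_factor, 1, 1)
}

#' Project the population one year with stochastic vital rates
#'
#' One annual step of the stochastic model: seven independent triangular
#' draws (four class survivals, three reproductive-class fertilities), then
#' `pups' = sum_j N_j S_j F_j / 2` over the reproductive classes and
#' subdiagonal advancement by the drawn survivals. Survival draws are capped
#' at 1; fertility draws are not (a good year may push expected offspring
#' per female above the central rate). With both stochasticity toggles off
#' the step reduces exactly to multiplication by the projection matrix.
#'
#' @param state Length-4 class vector at the start of the year.
#' @param rates A [vital_rates()] object.
#' @param fertility Central adult fertility for the year.
#' @param fmin,fmax Environmental fertility envelope for the year (defaults
#'   collapse to `fertility`).
#' @param config A [simulation_config()] (used for the toggles and
#'   half-width); any scenario inside it is ignored by this function.
#' @param u Optional vector of 7 uniforms to use instead of drawing from the
#'   RNG (order: survivals S_0..S_3+, then fertilities for the yearling,
#'   2 yr, 3+ columns).
#' @return Length-4 class vector at the start of the next year.
#' @export
project_one_year <- function(state, rates, fertility, fmin = fertility,
                             fmax = fertility, config, u = NULL) {
  stopifnot(length(state) == 4, all(state >= 0))
  if (is.null(u)) u <- stats::runif(7)
  stopifnot(length(u) == 7)

  st <- survival_triple(rates$survival, config)
  s <- qtriangular(u[1:4], st$lo, st$mid, st$hi)

  ft <- fertility_triple(fertility, fmin, fmax, config)
  mult <- class_fertility_multipliers(rates)[2:4]
  f <- qtriangular(u[5:7], ft$lo * mult, ft$mid * mult, ft$hi * mult)

  ratio <- rates$female_birth_ratio * rates$litter_size
  pups <- sum(state[2:4] * s[2:4] * f) * ratio
  c(pups,
    s[1] * state[1],
    s[2] * state[2],
    s[3] * state[3] + s[4] * state[4])
}

#' Run a Monte Carlo population simulation
#'
#' Projects `n_runs` independent replicates of the age-structured female
#' population over `n_years`, drawing one triangular deviate per (vital
#' rate, age class, year, replicate). Each replicate consumes its own child
#' random stream derived from the root seed, so a given `(seed, n_runs,
#' n_years)` triple is bit-reproducible and replicates are independent of
#' execution order. Population states are real-valued during projection
#' (the model randomises rates, not individual fates); per-replicate final
#' totals are rounded to the nearest female at reporting.
#'
#' @param config A [simulation_config()].
#' @return Object of class `simulation_result`: list with `finals` (rounded
#'   final totals per replicate), `summary` (one-row data.frame: mean,
#'   pct_change, min, max, sd), `scenario_name`, `n_runs`, `n_years`,
#'   `seed`, `initial_total`.
#' @examples
#' scen <- stable_scenario(vital_rates())
#' res <- run_simulation(simulation_config(scen, n_runs = 100, seed = 1))
#' res$summary
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  scen <- config$scenario
  n_runs <- config$n_runs
  n_years <- config$n_years
  rates <- config$rates
  initial_total <- sum(config$initial)

  if (n_years == 0) {
    finals <- rep(round(initial_total), n_runs)
    return(new_simulation_result(finals, initial_total, config))
  }

  # one child stream per replicate, derived by counter from the root seed
  set.seed(config$seed)
  child_seeds <- sample.int(.Machine$integer.max - 1L, n_runs)
  nd <- 7L * n_years
  U <- matrix(NA_real_, nd, n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(child_seeds[r])
    U[, r] <- stats::runif(nd)
  }

  st <- survival_triple(rates$survival, config)
  mult <- class_fertility_multipliers(rates)[2:4]
  ratio <- rates$female_birth_ratio * rates$litter_size

  N <- matrix(config$initial, 4, n_runs)
  for (y in seq_len(n_years)) {
    base <- (y - 1L) * 7L
    ft <- fertility_triple(scen$fertility[y], scen$fmin[y], scen$fmax[y],
                           config)
    s <- lapply(1:4, function(j)
      qtriangular(U[base + j, ], st$lo[j], st$mid[j], st$hi[j]))
    f <- lapply(1:3, function(k)
      qtriangular(U[base + 4L + k, ],
                  ft$lo * mult[k], ft$mid * mult[k], ft$hi * mult[k]))

    pups <- ratio * (N[2, ] * s[[2]] * f[[1]] +
                     N[3, ] * s[[3]] * f[[2]] +
                     N[4, ] * s[[4]] * f[[3]])
    N <- rbind(pups,
               s[[1]] * N[1, ],
               s[[2]] * N[2, ],
               s[[3]] * N[3, ] + s[[4]] * N[4, ])
  }

  finals <- round(colSums(N))
  new_simulation_result(finals, initial_total, config)
}

new_simulation_result <- function(finals, initial_total, config) {
  structure(
    list(finals = finals,
         summary = summarize_simulation(finals, initial_total),
         scenario_name = attr(config$scenario, "name"),
         rcp = attr(config$scenario, "rcp"),
         n_runs = config$n_runs, n_years = config$n_years,
         seed = config$seed, initial_total = initial_total),
    class = "simulation_result"
  )
}

#' Summarise replicate final populations
#'
#' The standard summary row: mean, percent change relative to the initial
#' total, minimum, maximum, and sample standard deviation (n - 1
#' denominator) of the replicate final totals.
#'
#' @param finals Numeric vector of per-replicate final totals (>= 1 value).
#' @param initial_total Initial population total (default 2,000 females).
#' @return One-row data.frame with columns `mean`, `pct_change`, `min`,
#'   `max`, `sd`.
#' @export
summarize_simulation <- function(finals, initial_total = 2000) {
  if (length(finals) < 1) stop("no replicates to summarise", call. = FALSE)
  m <- mean(finals)
  data.frame(
    mean = m,
    pct_change = 100 * (m - initial_total) / initial_total,
    min = min(finals),
    max = max(finals),
    sd = stats::sd(finals)
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s (%s): %d runs x %d years, seed %d\n",
              x$scenario_name, x$rcp, x$n_runs, x$n_years, x$seed))
  cat(sprintf("  mean %.0f (%+.2f%%), min %.0f, max %.0f, sd %.1f\n",
              s$mean, s$pct_change, s$min, s$max, s$sd))
  invisible(x)
}
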