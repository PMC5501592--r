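#' Logistic climate-fertility coefficients
#'
#' Coefficients of the binary logistic model
#' `Pr(reproductively active) = plogis(beta0 + betaT * T + betaP * P)`,
#' where T is mean annual temperature (deg C) and P annual precipitation
#' (mm). The default triple (2.6419, -0.2534, 0.0040) is the package's
#' reference Boulder-area fit: the probability of reproduction falls in
#' hotter years and rises in wetter ones.
#'
#' @param beta0 Intercept (logit units).
#' @param betaT Temperature coefficient (logit units per deg C).
#' @param betaP Precipitation coefficient (logit units per mm).
#' @return A named numeric vector of class `logistic_coefficients`.
#' @examples
#' predict_fertility(logistic_coefficients(), T = 10.85, P = 541)
#' @export
logistic_coefficients <- function(beta0 = 2.6419, betaT = -0.2534,
                                  betaP = 0.0040) {
  b <- c(beta0 = beta0, betaT = betaT, betaP = betaP)
  if (!is.numeric(b) || length(b) != 3 || any(!is.finite(b))) {
    stop("coefficients must be three finite numbers", call. = FALSE)
  }
  structure(b, class = "logistic_coefficients")
}

#' Predicted probability that an adult female reproduces
#'
#' Inverse-logit of `beta0 + betaT * T + betaP * P`. Vectorised over T and P
#' (recycled against each other).
#'
#' @param coefficients A [logistic_coefficients()] object (or length-3
#'   numeric in the order beta0, betaT, betaP).
#' @param T Mean annual temperature, deg C.
#' @param P Annual precipitation, mm.
#' @return Probabilities in (0, 1).
#' @export
predict_fertility <- function(coefficients, T, P) {
  b <- as.numeric(coefficients)
  if (length(b) != 3 || any(!is.finite(b))) {
    stop("coefficients must be three finite numbers", call. = FALSE)
  }
  if (any(!is.finite(T)) || any(!is.finite(P))) {
    stop("climate covariates must be finite", call. = FALSE)
  }
  stats::plogis(b[1] + b[2] * T + b[3] * P)
}

#' Scale an adult fertility prediction to an age class
#'
#' Yearlings reproduce at `yearling_factor` (default 0.9) times the adult
#' probability; two-year-old and older classes at the adult probability;
#' pups not at all.
#'
#' @param adult_prediction Adult reproduction probability (in \[0, 1\]).
#' @param class_label `"adult"`, `"yearling"`, or `"pup"`.
#' @param yearling_factor Yearling discount (default 0.9).
#' @return Per-class fertility probability.
#' @export
class_fertility <- function(adult_prediction,
                            class_label = c("adult", "yearling", "pup"),
                            yearling_factor = 0.9) {
  class_label <- match.arg(class_label)
  if (any(adult_prediction < 0) || any(adult_prediction > 1)) {
    stop("adult_prediction must lie in [0, 1]", call. = FALSE)
  }
  switch(class_label,
         adult    = adult_prediction,
         yearling = yearling_factor * adult_prediction,
         pup      = 0 * adult_prediction)
}

#' Fit the binary logistic climate-fertility model
#'
#' Maximum-likelihood logistic regression of reproductive status on climate
#' covariates, fitted by iteratively reweighted least squares
#' (`stats::glm`, binomial family, logit link) with convergence tolerance
#' 1e-8 on the deviance. Accepts either per-individual records (column
#' `status` in \{0, 1\}) or grouped year-level counts (columns `successes`
#' and `trials`); the two inputs are likelihood-equivalent up to a constant
#' and give identical coefficients.
#'
#' Complete or quasi-complete separation (fitted probabilities numerically 0
#' or 1, or a non-converged fit) raises an explicit error rather than
#' returning a silently divergent estimate.
#'
#' @param records Data frame with covariate columns (default `T`, `P`) and
#'   either `status` or `successes` + `trials`.
#' @param covariates Character vector of covariate column names; use
#'   `character(0)` for an intercept-only fit.
#' @param tol IRLS convergence tolerance (default 1e-8).
#' @return Object of class `fertility_fit`: list with `coefficients` (named
#'   beta0/betaT/betaP for the default covariates), `se`, `log_likelihood`,
#'   `fitted`, `n`, and the underlying `glm` object as `fit`.
#' @examples
#' spec <- synthetic_spec(seed = 1)
#' recs <- gen_repro_records(spec)
#' fit_fertility_model(recs)$coefficients
#' @export
fit_fertility_model <- function(records, covariates = c("T", "P"),
                                tol = 1e-8) {
  stopifnot(is.data.frame(records))
  grouped <- all(c("successes", "trials") %in% names(records))
  if (!grouped && !("status" %in% names(records))) {
    stop("records need a 'status' column or 'successes' + 'trials' columns",
         call. = FALSE)
  }
  missing_cov <- setdiff(covariates, names(records))
  if (length(missing_cov)) {
    stop("missing covariate columns: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }

  if (grouped) {
    if (any(records$trials < 1) || any(records$successes < 0) ||
        any(records$successes > records$trials)) {
      stop("grouped records need 0 <= successes <= trials, trials >= 1",
           call. = FALSE)
    }
    response <- "cbind(successes, trials - successes)"
    n_total <- sum(records$trials)
    n_succ <- sum(records$successes)
  } else {
    if (!all(records$status %in% c(0, 1))) {
      stop("status must be binary (0/1)", call. = FALSE)
    }
    response <- "status"
    n_total <- nrow(records)
    n_succ <- sum(records$status)
  }
  if (n_succ == 0 || n_succ == n_total) {
    stop("separation: all outcomes are ", as.integer(n_succ > 0),
         "; the logistic model is not identifiable", call. = FALSE)
  }
  if (length(covariates)) {
    patterns <- unique(records[covariates])
    if (nrow(patterns) < 2) {
      stop("need >= 2 distinct covariate patterns to fit covariates",
           call. = FALSE)
    }
  }

  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(response, "~", rhs))

  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial("logit"), data = records,
               control = stats::glm.control(epsilon = tol, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separation || any(stats::fitted(fit) < 1e-8) ||
      any(stats::fitted(fit) > 1 - 1e-8)) {
    stop("separation: fitted probabilities numerically 0 or 1; ",
         "coefficient estimates diverge", call. = FALSE)
  }
  if (!fit$converged) {
    stop("IRLS did not converge within 100 iterations", call. = FALSE)
  }
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient design: some coefficients are not estimable",
         call. = FALSE)
  }

  est <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  nm <- c("beta0", if (length(covariates))
    paste0("beta", ifelse(covariates %in% c("T", "P"),
                          covariates, covariates)))
  names(est) <- names(se) <- nm

  structure(
    list(coefficients = est, se = se,
         log_likelihood = as.numeric(stats::logLik(fit)),
         fitted = stats::fitted(fit),
         n = n_total, covariates = covariates, fit = fit),
    class = "fertility_fit"
  )
}

#' @export
print.fertility_fit <- function(x, ...) {
  cat("Logistic climate-fertility fit (n =", x$n, ")\n")
  tab <- cbind(estimate = x$coefficients, se = x$se)
  print(round(tab, 4))
  cat(sprintf("log-likelihood: %.3f\n", x$log_likelihood))
  invisible(x)
}

#' Coefficients of a fertility fit as logistic_coefficients
#'
#' @param fit A `fertility_fit` with covariates `T` and `P`.
#' @return A [logistic_coefficients()] object.
#' @export
as_logistic_coefficients <- function(fit) {
  stopifnot(inherits(fit, "fertility_fit"))
  if (!identical(fit$covariates, c("T", "P"))) {
    stop("fit must use covariates T and P", call. = FALSE)
  }
  logistic_coefficients(fit$coefficients[["beta0"]],
                        fit$coefficients[["betaT"]],
                        fit$coefficients[["betaP"]])
}
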