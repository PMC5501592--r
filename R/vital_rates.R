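#' Age classes used throughout the package
#'
#' Four classes: pups (0--1 yr), yearlings (1 yr), two-year-olds (2 yr), and
#' the terminal three-years-and-older class (3+ yr).
#'
#' @format Character vector of length 4.
#' @export
BAT_CLASSES <- c("0-1yr", "1yr", "2yr", "3+yr")

#' Vital rates for the four-class bat demographic model
#'
#' Bundles annual survival and fertility probabilities for an age-structured
#' female-only model of a long-lived, single-pup bat. Defaults are the
#' package's reference parameterisation for fringed myotis in the Colorado
#' Front Range: adult survival 0.79, first-year (pup) survival 0.64, adult
#' fertility 0.85, yearling fertility 90% of adult, 1:1 birth sex ratio, and
#' single-pup litters.
#'
#' Per-class vectors index the class an individual occupies at the annual
#' census. The pup class does not reproduce (its fertility defaults to 0);
#' the yearling class reproduces at `yearling_factor * adult_fertility`; the
#' 2 yr and 3+ yr classes reproduce at `adult_fertility`.
#'
#' @param pup_survival Probability a newborn survives to its first birthday
#'   (per year).
#' @param adult_survival Probability a bat 1 yr or older survives the year.
#' @param adult_fertility Probability a reproductive-age female produces a
#'   viable pup in a year.
#' @param yearling_factor Yearling fertility as a fraction of adult fertility
#'   (default 0.90).
#' @param survival Optional length-4 numeric overriding per-class survivals
#'   (S_0, S_1, S_2, S_3+). Defaults derive S_0 from `pup_survival` and the
#'   rest from `adult_survival`.
#' @param fertility Optional length-4 numeric overriding per-class fertilities
#'   (F_0, F_1, F_2, F_3+), indexed by census class. Defaults are
#'   (0, yearling_factor * F_A, F_A, F_A).
#' @param female_birth_ratio Proportion of births that are female (default
#'   0.5, parity).
#' @param litter_size Mean pups per birth (default 1; the model assumes
#'   single pups).
#'
#' @return An object of class `vital_rates`: a list with elements
#'   `survival` (named length-4), `fertility` (named length-4),
#'   `adult_fertility`, `yearling_factor`, `female_birth_ratio`,
#'   `litter_size`.
#' @examples
#' r <- vital_rates()
#' r$survival
#' expected_offspring(r, "adult")
#' @export
vital_rates <- function(pup_survival = 0.64,
                        adult_survival = 0.79,
                        adult_fertility = 0.85,
                        yearling_factor = 0.90,
                        survival = NULL,
                        fertility = NULL,
                        female_birth_ratio = 0.5,
                        litter_size = 1.0) {
  check_prob(pup_survival, "pup_survival")
  check_prob(adult_survival, "adult_survival")
  check_prob(adult_fertility, "adult_fertility")
  check_prob(yearling_factor, "yearling_factor")
  check_prob(female_birth_ratio, "female_birth_ratio")
  if (!is.numeric(litter_size) || length(litter_size) != 1 ||
      !is.finite(litter_size) || litter_size < 0) {
    stop("litter_size must be a single non-negative number", call. = FALSE)
  }

  if (is.null(survival)) {
    survival <- c(pup_survival, adult_survival, adult_survival, adult_survival)
  }
  if (is.null(fertility)) {
    fertility <- c(0, yearling_factor * adult_fertility,
                   adult_fertility, adult_fertility)
  }
  if (length(survival) != 4) stop("survival must have length 4", call. = FALSE)
  if (length(fertility) != 4) stop("fertility must have length 4", call. = FALSE)
  for (i in 1:4) {
    check_prob(survival[i], paste0("survival[", BAT_CLASSES[i], "]"))
    check_prob(fertility[i], paste0("fertility[", BAT_CLASSES[i], "]"))
  }
  names(survival) <- names(fertility) <- BAT_CLASSES

  structure(
    list(survival = survival,
         fertility = fertility,
         adult_fertility = adult_fertility,
         yearling_factor = yearling_factor,
         female_birth_ratio = female_birth_ratio,
         litter_size = litter_size),
    class = "vital_rates"
  )
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("%s must be a single probability in [0, 1] (got %s)",
                 name, format(x)), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.vital_rates <- function(x, ...) {
  cat("Vital rates (female, per year)\n")
  cat("  survival :", paste(sprintf("%s=%.3f", names(x$survival), x$survival),
                            collapse = "  "), "\n")
  cat("  fertility:", paste(sprintf("%s=%.3f", names(x$fertility), x$fertility),
                            collapse = "  "), "\n")
  cat(sprintf("  female birth ratio %.2f, litter size %.2f\n",
              x$female_birth_ratio, x$litter_size))
  invisible(x)
}

#' Expected female offspring per female per year
#'
#' The worked expectation E[O] = female_birth_ratio x fertility x litter size,
#' with the yearling class discounted by the yearling factor. For the default
#' rates E[O_A] = 0.5 x 0.85 = 0.425 and E[O_Y] = 0.5 x 0.85 x 0.9 = 0.3825.
#' These products deliberately exclude maternal survival; the projection
#' matrix's first-row entries additionally multiply by survival because births
#' are censused after the mother's year of survival.
#'
#' @param rates A [vital_rates()] object.
#' @param class_label `"adult"` (2 yr and 3+ classes), `"yearling"`, or
#'   `"pup"`.
#' @return Expected female pups per female per year (numeric scalar).
#' @export
expected_offspring <- function(rates, class_label = c("adult", "yearling", "pup")) {
  stopifnot(inherits(rates, "vital_rates"))
  class_label <- match.arg(class_label)
  base <- rates$female_birth_ratio * rates$adult_fertility * rates$litter_size
  switch(class_label,
         adult    = base,
         yearling = base * rates$yearling_factor,
         pup      = 0)
}

#' Read vital rates from a JSON or YAML key-value file
#'
#' Recognised keys match the arguments of [vital_rates()]; missing keys fall
#' back to the defaults. The format is chosen by file extension
#' (`.json` vs `.yaml`/`.yml`).
#'
#' @param path Path to the file.
#' @return A [vital_rates()] object.
#' @export
read_vital_rates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported vital-rate file extension: .", ext, call. = FALSE)
  )
  allowed <- names(formals(vital_rates))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown)) {
    stop("unknown vital-rate fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  do.call(vital_rates, vals)
}
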