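#' Build the four-class projection matrix
#'
#' Assembles the Leslie-type annual projection matrix A from vital rates.
#' The census falls on day 1 of each year and births on the last day, so a
#' female counted in class j contributes newborn females
#' `a_1j = S_j * F_j * female_birth_ratio * litter_size` (she must survive
#' the year before giving birth). Survivors advance along the subdiagonal
#' (`a_21 = S_0`, `a_32 = S_1`, `a_43 = S_2`) and the terminal class retains
#' itself (`a_44 = S_3+`). Pups do not reproduce, so `a_11 = 0` under the
#' default fertilities.
#'
#' @param rates A [vital_rates()] object.
#' @return A 4x4 numeric matrix of class `projection_matrix` with the class
#'   labels as dimnames and the originating rates attached as attribute
#'   `"rates"`.
#' @examples
#' A <- projection_matrix(vital_rates())
#' A[2, 1]   # pup survival, 0.64
#' @export
projection_matrix <- function(rates) {
  stopifnot(inherits(rates, "vital_rates"))
  S <- rates$survival
  f <- rates$fertility * rates$female_birth_ratio * rates$litter_size
  A <- matrix(0, 4, 4, dimnames = list(BAT_CLASSES, BAT_CLASSES))
  A[1, ] <- S * f
  A[2, 1] <- S[1]
  A[3, 2] <- S[2]
  A[4, 3] <- S[3]
  A[4, 4] <- S[4]
  structure(A, class = c("projection_matrix", "matrix", "array"),
            rates = rates)
}

#' @export
print.projection_matrix <- function(x, ...) {
  cat("Annual projection matrix (females):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

as_matrix <- function(A) {
  m <- unclass(A)
  attr(m, "rates") <- NULL
  m
}

#' Dominant eigenvalue and stable age distribution
#'
#' Computes the asymptotic per-year growth rate lambda (spectral radius) and
#' the stable age distribution w (dominant right eigenvector scaled to sum
#' to 1) of a non-negative projection matrix. Uses a dense eigen
#' decomposition with tie-breaking by modulus then real part; if the
#' decomposition leaves a materially complex dominant root (possible only
#' for imprimitive matrices), a power-iteration fallback is used.
#'
#' @param A A `projection_matrix` or plain non-negative square matrix.
#' @return An object of class `eigen_analysis`: list with `lambda`,
#'   `stable_distribution` (length-4, sums to 1), and `left_vector`
#'   (reproductive values, scaled so the first entry is 1).
#' @examples
#' eigen_analysis(projection_matrix(vital_rates()))$lambda
#' @export
eigen_analysis <- function(A) {
  m <- as_matrix(A)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("A must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("A must be non-negative and finite", call. = FALSE)
  }
  if (all(m == 0)) {
    stop("all-zero matrix has no dominant eigenvalue of interest",
         call. = FALSE)
  }

  dominant <- function(mat) {
    e <- eigen(mat)
    ord <- order(-Mod(e$values), -Re(e$values))
    k <- ord[1]
    list(value = e$values[k], vector = e$vectors[, k])
  }

  dr <- dominant(m)
  if (abs(Im(dr$value)) > 1e-8 * max(1, Mod(dr$value))) {
    # imprimitive matrix: fall back to power iteration on (A + I) which
    # shares eigenvectors and shifts all eigenvalues by +1
    pi_fit <- power_iteration_internal(m + diag(nrow(m)))
    lambda <- pi_fit$lambda - 1
    w <- pi_fit$w
  } else {
    lambda <- Re(dr$value)
    w <- Re(dr$vector)
  }
  if (sum(w) < 0) w <- -w
  if (any(w < -1e-10)) {
    # mixed-sign vector cannot be a stable distribution; retry by power iteration
    pi_fit <- power_iteration_internal(m + diag(nrow(m)))
    lambda <- pi_fit$lambda - 1
    w <- pi_fit$w
  }
  w <- pmax(w, 0)
  w <- w / sum(w)

  dl <- dominant(t(m))
  v <- Re(dl$vector)
  if (v[1] < 0) v <- -v
  if (abs(v[1]) > 0) v <- v / v[1]

  structure(list(lambda = lambda, stable_distribution = w, left_vector = v),
            class = "eigen_analysis")
}

power_iteration_internal <- function(m, tol = 1e-14, maxit = 100000L) {
  w <- rep(1, nrow(m))
  lambda <- NA_real_
  for (i in seq_len(maxit)) {
    w2 <- as.vector(m %*% w)
    lambda2 <- sum(w2)
    if (lambda2 == 0) stop("power iteration collapsed to zero", call. = FALSE)
    w2 <- w2 / lambda2
    if (max(abs(w2 - w)) < tol) {
      return(list(lambda = lambda2, w = w2))
    }
    w <- w2
    lambda <- lambda2
  }
  list(lambda = lambda, w = w)
}

#' @export
print.eigen_analysis <- function(x, ...) {
  cat(sprintf("lambda = %.6f\n", x$lambda))
  cat("stable age distribution:",
      paste(sprintf("%.4f", x$stable_distribution), collapse = " "), "\n")
  invisible(x)
}

# Parameter label -> matrix element. Each vital rate perturbs exactly one
# element: survivals their transition entry, fertilities their class's
# first-row entry (the pup class's entry is structurally zero).
PERTURBATION_MAP <- list(
  F_0     = c(1, 1), F_1 = c(1, 2), F_2 = c(1, 3), F_3plus = c(1, 4),
  S_0     = c(2, 1), S_1 = c(3, 2), S_2 = c(4, 3), S_3plus = c(4, 4)
)

#' Finite-difference sensitivity and elasticity of lambda
#'
#' Perturbs the single matrix element associated with one vital rate by a
#' proportional `fraction` (default -10%, i.e. rate x 0.90), recomputes the
#' dominant eigenvalue, and reports the finite-difference sensitivity
#' `(lambda' - lambda) / (a' - a)` and elasticity `sensitivity * a / lambda`.
#' A structurally zero element cannot change under a proportional
#' perturbation; its sensitivity and elasticity are reported as 0.
#'
#' @param A A `projection_matrix` (or non-negative matrix).
#' @param parameter One of `"F_0"`, `"F_1"`, `"F_2"`, `"F_3plus"`, `"S_0"`,
#'   `"S_1"`, `"S_2"`, `"S_3plus"`.
#' @param fraction Proportional change applied to the element (default -0.10;
#'   must be nonzero).
#' @return An object of class `perturbation_result`: list with `parameter`,
#'   `element` (row, col), `sensitivity`, `elasticity`, `fraction`,
#'   `lambda_base`, `lambda_perturbed`.
#' @examples
#' perturbation_analysis(projection_matrix(vital_rates()), "S_2")$elasticity
#' @export
perturbation_analysis <- function(A, parameter, fraction = -0.10) {
  if (!is.character(parameter) || length(parameter) != 1 ||
      is.na(match(parameter, names(PERTURBATION_MAP)))) {
    stop("unknown parameter: ", paste(parameter, collapse = ", "),
         "; expected one of ", paste(names(PERTURBATION_MAP), collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(fraction) || length(fraction) != 1 || !is.finite(fraction) ||
      fraction == 0) {
    stop("fraction must be a single nonzero number", call. = FALSE)
  }
  m <- as_matrix(A)
  el <- PERTURBATION_MAP[[parameter]]
  a0 <- m[el[1], el[2]]
  lambda0 <- eigen_analysis(m)$lambda

  if (a0 == 0) {
    sens <- 0
    elas <- 0
    lambda1 <- lambda0
  } else {
    m1 <- m
    m1[el[1], el[2]] <- a0 * (1 + fraction)
    lambda1 <- eigen_analysis(m1)$lambda
    sens <- (lambda1 - lambda0) / (m1[el[1], el[2]] - a0)
    elas <- sens * a0 / lambda0
  }

  structure(list(parameter = parameter, element = el,
                 sensitivity = sens, elasticity = elas,
                 fraction = fraction,
                 lambda_base = lambda0, lambda_perturbed = lambda1),
            class = "perturbation_result")
}

#' @export
print.perturbation_result <- function(x, ...) {
  cat(sprintf("%s (a[%d,%d], %+.0f%%): sensitivity %.4f, elasticity %.4f\n",
              x$parameter, x$element[1], x$element[2], 100 * x$fraction,
              x$sensitivity, x$elasticity))
  invisible(x)
}

#' Finite-difference sensitivity/elasticity table for all vital rates
#'
#' Runs [perturbation_analysis()] for every vital-rate label and returns the
#' rows in the conventional order (fertilities then survivals by age).
#'
#' @inheritParams perturbation_analysis
#' @param parameters Labels to include (default all eight).
#' @return A data.frame with columns `parameter`, `sensitivity`, `elasticity`.
#' @export
elasticity_table <- function(A, parameters = names(PERTURBATION_MAP),
                             fraction = -0.10) {
  rows <- lapply(parameters, function(p) {
    r <- perturbation_analysis(A, p, fraction)
    data.frame(parameter = p, sensitivity = r$sensitivity,
               elasticity = r$elasticity)
  })
  do.call(rbind, rows)
}

#' Analytic sensitivity and elasticity matrices
#'
#' The classical eigenvector formulas: `s_ij = v_i w_j / <v, w>` and
#' `e_ij = (a_ij / lambda) s_ij`, with v and w the dominant left and right
#' eigenvectors. Elasticities of a primitive matrix sum to 1 over all
#' elements.
#'
#' @param A A `projection_matrix` (or non-negative matrix).
#' @return List with matrices `sensitivity` and `elasticity`, plus `lambda`.
#' @export
analytic_elasticity <- function(A) {
  m <- as_matrix(A)
  ea <- eigen_analysis(m)
  v <- ea$left_vector
  w <- ea$stable_distribution
  S <- outer(v, w) / sum(v * w)
  E <- S * m / ea$lambda
  dimnames(S) <- dimnames(E) <- dimnames(m)
  list(sensitivity = S, elasticity = E, lambda = ea$lambda)
}

#' Deterministic multi-year projection
#'
#' Applies the projection matrix repeatedly to an initial class vector,
#' without stochasticity.
#'
#' @param A A `projection_matrix` (or non-negative matrix).
#' @param initial Length-4 non-negative class vector at year 0.
#' @param n_years Number of annual steps.
#' @return A `(n_years + 1) x 4` matrix of class counts, year 0 first.
#' @export
project_population <- function(A, initial, n_years) {
  m <- as_matrix(A)
  stopifnot(length(initial) == nrow(m), all(initial >= 0), n_years >= 0)
  out <- matrix(NA_real_, n_years + 1, nrow(m),
                dimnames = list(NULL, colnames(m)))
  out[1, ] <- initial
  state <- initial
  for (t in seq_len(n_years)) {
    state <- as.vector(m %*% state)
    out[t + 1, ] <- state
  }
  out
}
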