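# Multidimensional graded response model data generator and the Monte
# Carlo oracle for population item-score reliability.
#
# P(Xi >= x | theta) = logistic( sum_q alpha_iq (theta_q - delta_ix) ),
# theta ~ Q-variate standard normal with a given correlation matrix.

#' Cumulative response probability of the graded response model
#'
#' @param theta latent trait vector (length Q) or an N x Q matrix.
#' @param alpha_row discrimination vector of the item (length Q).
#' @param delta category location (scalar).
#' @return probability (vector of length N for matrix input).
#' @export
grm_cumulative <- function(theta, alpha_row, delta) {
  if (!is.matrix(theta)) theta <- matrix(theta, nrow = 1L)
  stopifnot(ncol(theta) == length(alpha_row))
  lin <- drop(sweep(theta, 2L, delta) %*% alpha_row)
  stats::plogis(lin)
}

std_delta <- c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5)

#' Simulation condition of the graded response model design
#'
#' Six named presets mirror the simulation design: \code{"standard"} (six
#' dichotomous items, one dimension, all discriminations 1, locations
#' equidistant from -1.5 to 1.5, N = 1000), \code{"polytomous"} (m = 4,
#' the four-column location grid), \code{"unequal_alpha"} (discriminations
#' alternating 0.5 and 2), \code{"two_dim"} (two latent variables
#' correlating .5, items loading on alternating dimensions),
#' \code{"long_test"} (the standard items appearing three times in total,
#' J = 18) and \code{"small_n"} (standard with N = 200).
#'
#' @param name preset name, or any string when all parameters are supplied.
#' @param J,m,Q,N design sizes (items, max score, dimensions, persons).
#' @param alpha J x Q discrimination matrix.
#' @param delta J x m location matrix, rows strictly increasing.
#' @param theta_cor Q x Q latent correlation matrix.
#' @param replications default replication count for the study harness.
#' @return object of class \code{"grm_condition"}.
#' @export
grm_condition <- function(name = "standard", J = NULL, m = NULL, Q = NULL,
                          N = NULL, alpha = NULL, delta = NULL,
                          theta_cor = NULL, replications = 1000) {
  presets <- list(
    standard = list(J = 6L, m = 1L, Q = 1L, N = 1000L,
                    alpha = matrix(1, 6, 1),
                    delta = matrix(std_delta, 6, 1)),
    polytomous = list(J = 6L, m = 4L, Q = 1L, N = 1000L,
                      alpha = matrix(1, 6, 1),
                      delta = rbind(c(-3, -2, -1, 0),
                                    c(-2.4, -1.4, -0.4, 0.6),
                                    c(-1.8, -0.8, 0.2, 1.2),
                                    c(-1.2, -0.2, 0.8, 1.8),
                                    c(-0.6, 0.4, 1.4, 2.4),
                                    c(0, 1, 2, 3))),
    unequal_alpha = list(J = 6L, m = 1L, Q = 1L, N = 1000L,
                         alpha = matrix(c(0.5, 2, 0.5, 2, 0.5, 2), 6, 1),
                         delta = matrix(std_delta, 6, 1)),
    two_dim = list(J = 6L, m = 1L, Q = 2L, N = 1000L,
                   alpha = matrix(c(1, 0, 1, 0, 1, 0,
                                    0, 1, 0, 1, 0, 1), 6, 2),
                   delta = matrix(std_delta, 6, 1),
                   theta_cor = matrix(c(1, .5, .5, 1), 2, 2)),
    long_test = list(J = 18L, m = 1L, Q = 1L, N = 1000L,
                     alpha = matrix(1, 18, 1),
                     delta = matrix(rep(std_delta, 3), 18, 1)),
    small_n = list(J = 6L, m = 1L, Q = 1L, N = 200L,
                   alpha = matrix(1, 6, 1),
                   delta = matrix(std_delta, 6, 1))
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    if (is.null(J)) J <- p$J
    if (is.null(m)) m <- p$m
    if (is.null(Q)) Q <- p$Q
    if (is.null(N)) N <- p$N
    if (is.null(alpha)) alpha <- p$alpha
    if (is.null(delta)) delta <- p$delta
    if (is.null(theta_cor)) theta_cor <- p$theta_cor
  }
  if (is.null(theta_cor)) theta_cor <- diag(Q)
  alpha <- as.matrix(alpha); delta <- as.matrix(delta)
  theta_cor <- as.matrix(theta_cor)
  if (is.null(J) || is.null(m) || is.null(Q) || is.null(N))
    stop("custom conditions must supply J, m, Q and N", call. = FALSE)
  stopifnot(nrow(alpha) == J, ncol(alpha) == Q,
            nrow(delta) == J, ncol(delta) == m,
            nrow(theta_cor) == Q, ncol(theta_cor) == Q)
  if (m > 1L && any(apply(delta, 1L, function(d) any(diff(d) <= 0))))
    stop("location parameters must be strictly increasing within each item",
         call. = FALSE)
  if (!isSymmetric(unname(theta_cor)) ||
      any(abs(diag(theta_cor) - 1) > 1e-12) ||
      any(eigen(theta_cor, symmetric = TRUE, only.values = TRUE)$values <= 0))
    stop("theta_cor must be a symmetric positive definite correlation matrix",
         call. = FALSE)
  structure(list(name = name, J = as.integer(J), m = as.integer(m),
                 Q = as.integer(Q), N = as.integer(N), alpha = alpha,
                 delta = delta, theta_cor = theta_cor,
                 replications = as.integer(replications)),
            class = "grm_condition")
}

#' @export
print.grm_condition <- function(x, ...) {
  cat(sprintf("grm_condition '%s': J = %d, m = %d, Q = %d, N = %d\n",
              x$name, x$J, x$m, x$Q, x$N))
  invisible(x)
}

#' Names of the built-in simulation condition presets
#' @return character vector.
#' @export
grm_preset_names <- function() {
  c("standard", "polytomous", "unequal_alpha", "two_dim", "long_test",
    "small_n")
}

#' Read a condition from a JSON configuration file
#'
#' Fields as in \code{\link{grm_condition}}; \code{alpha}, \code{delta} and
#' \code{theta_cor} are row-major nested arrays.
#'
#' @param path JSON file path.
#' @return a \code{"grm_condition"}.
#' @export
read_grm_condition <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  grm_condition(name = cfg$name %||% "custom", J = cfg$J, m = cfg$m,
                Q = cfg$Q, N = cfg$N, alpha = cfg$alpha, delta = cfg$delta,
                theta_cor = cfg$theta_cor,
                replications = cfg$replications %||% 1000)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

draw_theta <- function(n, cond) {
  Z <- matrix(stats::rnorm(n * cond$Q), n, cond$Q)
  if (cond$Q > 1L) Z <- Z %*% chol(cond$theta_cor)
  Z
}

# N x m matrix of P(Xi >= x | theta) for one item over all simulees
item_cumprobs <- function(theta, cond, item) {
  vapply(seq_len(cond$m), function(x)
    grm_cumulative(theta, cond$alpha[item, ], cond$delta[item, x]),
    numeric(nrow(theta)))
}

#' Simulate an item-score matrix from a condition
#'
#' Latent vectors are drawn from the (correlated) standard normal, and for
#' each person/item the score is drawn from the multinomial distribution
#' with category probabilities P(Xi = x | theta) = P(Xi >= x | theta) -
#' P(Xi >= x+1 | theta).  Bit-reproducible given (condition, seed).
#'
#' @param cond a \code{"grm_condition"}.
#' @param seed RNG seed.
#' @param N optional override of the condition's sample size.
#' @return an \code{item_scores} object (with the drawn \code{theta}
#'   attached as attribute \code{"theta"}).
#' @export
simulate_grm <- function(cond, seed = 1, N = NULL) {
  stopifnot(inherits(cond, "grm_condition"))
  if (is.null(N)) N <- cond$N
  set.seed(seed)
  theta <- draw_theta(N, cond)
  X <- matrix(0L, N, cond$J)
  for (i in seq_len(cond$J)) {
    pge <- item_cumprobs(theta, cond, i)     # N x m, nonincreasing in x
    u <- stats::runif(N)
    X[, i] <- as.integer(rowSums(u < pge))   # nested events: valid draw
  }
  out <- item_scores(X, m = cond$m)
  attr(out, "theta") <- theta
  out
}

#' Monte Carlo population item-score reliability of a condition
#'
#' Item scores are generated for \code{n_simulees} simulees; per item the
#' variance of the conditional expected item score
#' T_i = sum_x P(Xi >= x | theta) across simulees (the true-score variance)
#' is divided by the variance of the sampled item scores.
#'
#' @param cond a \code{"grm_condition"}.
#' @param n_simulees number of simulees (>= 1e4).
#' @param seed RNG seed.
#' @return named numeric vector of per-item reliabilities.
#' @export
population_item_reliability <- function(cond, n_simulees = 1e6, seed = 1) {
  stopifnot(inherits(cond, "grm_condition"))
  if (n_simulees < 1e4) stop("use at least 10^4 simulees", call. = FALSE)
  set.seed(seed)
  theta <- draw_theta(n_simulees, cond)
  rho <- numeric(cond$J)
  for (i in seq_len(cond$J)) {
    pge <- item_cumprobs(theta, cond, i)
    Ti <- rowSums(pge)
    u <- stats::runif(n_simulees)
    Xi <- rowSums(u < pge)
    rho[i] <- stats::var(Ti) / stats::var(Xi)
  }
  stats::setNames(rho, paste0("V", seq_len(cond$J)))
}
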