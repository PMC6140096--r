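# Deterministic fixture generators shared across test files.  These are
# written in base R only (independent of the package's own simulator) so
# that frozen oracle values computed against external reference
# implementations stay tied to the data, not to package internals.

# Graded-style polytomous scores: one latent trait, logistic item steps,
# nested category events (single uniform per person/item).
fix_scores <- function(N, J, m, seed) {
  set.seed(seed)
  th <- stats::rnorm(N)
  X <- vapply(seq_len(J), function(j) {
    d <- seq(-1.2, 1.2, length.out = m) + 0.3 * j - 0.15 * (J + 1)
    p <- vapply(d, function(dd) stats::plogis(th - dd), numeric(N)) # N x m
    u <- stats::runif(N)
    as.integer(rowSums(u < p))
  }, integer(N))
  X
}

# The four-item artificial example: marginal cumulative probabilities and
# the observable joint cumulative probabilities of the ordered 8 x 8 P(++)
# table, keyed by item steps.
fix_artificial_example <- function() {
  marg <- rbind(c(.97, .53), c(.94, .32), c(.93, .85), c(.86, .72))
  steps <- list(c(2L, 2L), c(1L, 2L), c(4L, 2L), c(3L, 2L),
                c(4L, 1L), c(3L, 1L), c(2L, 1L), c(1L, 1L))  # (item, x)
  vals <- rbind(
    c(NA, .20, .27, .29, .30, .31, NA, .32),
    c(.20, NA, .41, .47, .48, .50, .51, NA),
    c(.27, .41, NA, .64, NA, .68, .68, .70),
    c(.29, .47, .64, NA, .76, NA, .81, .84),
    c(.30, .48, NA, .76, NA, .81, .81, .84),
    c(.31, .50, .68, NA, .81, NA, .88, .91),
    c(NA, .51, .68, .81, .81, .88, NA, .91),
    c(.32, NA, .70, .84, .84, .91, .91, NA))
  joint <- array(NA_real_, c(2, 2, 4, 4))
  for (r in 1:8) for (cc in 1:8) {
    s1 <- steps[[r]]; s2 <- steps[[cc]]
    if (s1[1L] != s2[1L])
      joint[s1[2L], s2[2L], s1[1L], s2[1L]] <- vals[r, cc]
  }
  list(marginal = marg, joint = joint)
}

# Table-5-style two- and three-class dichotomous models, replicated over
# J conditionally independent items.
fix_two_class_model <- function(J = 6L) {
  itemrel::latent_class_model(c(.4, .6),
                              matrix(c(.5, .8), J, 2, byrow = TRUE))
}

fix_three_class_model <- function(J = 6L) {
  itemrel::latent_class_model(c(.4, .3, .3),
                              matrix(c(.5, .6, 1.0), J, 3, byrow = TRUE))
}

# Continuous data whose SAMPLE covariance matrix equals S exactly
# (orthogonalize, then rotate): lets covariance-based closed forms be
# asserted at machine precision.
fix_exact_cov <- function(N, S, seed) {
  J <- ncol(S)
  set.seed(seed)
  Z <- scale(matrix(stats::rnorm(N * J), N, J), center = TRUE, scale = FALSE)
  Z <- Z %*% backsolve(chol(stats::cov(Z)), diag(J))
  Z %*% chol(S)
}

# Essentially tau-equivalent integer items: common binomial true score plus
# independent binomial noise.  Item reliability = Var(B) / Var(Xi) =
# 1 / 1.5, inter-item covariance = Var(B) = 1.
fix_tau_equivalent <- function(N, J, seed) {
  set.seed(seed)
  B <- stats::rbinom(N, 4L, .5)
  vapply(seq_len(J), function(j) B + stats::rbinom(N, 2L, .5), integer(N))
}
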