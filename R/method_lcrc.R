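# Latent class reliability coefficient: fit an unconstrained latent class
# model by EM, assemble the model-implied same-item joint cumulative
# probabilities, and feed them through the reliability assembly formula.

#' Construct a latent class model object
#'
#' @param weights length-K class probabilities P(xi = k), summing to 1.
#' @param response J x (m+1) x K array, \code{response[i, x+1, k]} =
#'   P(Xi = x | xi = k); each row sums to 1 over x.  A J x K matrix is
#'   accepted for dichotomous items and read as P(Xi = 1 | xi = k).
#' @param loglik,n_starts,seed,converged,loglik_trace fit metadata
#'   (optional for hand-specified models).
#' @return object of class \code{"latent_class_model"}.
#' @export
latent_class_model <- function(weights, response, loglik = NA_real_,
                               n_starts = NA_integer_, seed = NA_integer_,
                               converged = NA, loglik_trace = NULL) {
  weights <- as.numeric(weights)
  K <- length(weights)
  if (is.matrix(response)) {  # dichotomous shorthand: P(Xi=1|k)
    J <- nrow(response)
    resp <- array(NA_real_, c(J, 2L, K))
    resp[, 2L, ] <- response
    resp[, 1L, ] <- 1 - response
    response <- resp
  }
  stopifnot(length(dim(response)) == 3L, dim(response)[3L] == K)
  if (abs(sum(weights) - 1) > 1e-8 || any(weights < -1e-12))
    stop("class weights must be nonnegative and sum to 1", call. = FALSE)
  rs <- apply(response, c(1L, 3L), sum)
  if (any(abs(rs - 1) > 1e-8) || any(response < -1e-12))
    stop("response probabilities must be in [0,1] and sum to 1 over x",
         call. = FALSE)
  structure(list(K = K, weights = weights, response = response,
                 J = dim(response)[1L], m = dim(response)[2L] - 1L,
                 loglik = loglik, n_starts = n_starts, seed = seed,
                 converged = converged, loglik_trace = loglik_trace),
            class = "latent_class_model")
}

#' @export
print.latent_class_model <- function(x, digits = 3, ...) {
  cat(sprintf("latent_class_model: K = %d classes, J = %d items, m = %d\n",
              x$K, x$J, x$m))
  cat("weights:", round(x$weights, digits), "\n")
  if (is.finite(x$loglik))
    cat(sprintf("loglik %.4f (%s, %s starts)\n", x$loglik,
                if (isTRUE(x$converged)) "converged" else "NOT converged",
                x$n_starts))
  invisible(x)
}

# collapse data to distinct response patterns with counts
collapse_patterns <- function(data) {
  key <- apply(data, 1L, paste, collapse = ",")
  tab <- table(key)
  pat <- do.call(rbind, strsplit(names(tab), ",", fixed = TRUE))
  storage.mode(pat) <- "integer"
  list(patterns = pat, counts = as.integer(tab))
}

# P x (J*(m+1)) indicator matrix of (item, category) membership per
# pattern; lets both EM steps run as single matrix products
pattern_indicator <- function(patterns, m) {
  P <- nrow(patterns); J <- ncol(patterns)
  C <- matrix(0, P, J * (m + 1L))
  for (j in seq_len(J))
    C[cbind(seq_len(P), (j - 1L) * (m + 1L) + patterns[, j] + 1L)] <- 1
  C
}

# log P(pattern p | class k) for all patterns/classes; resp_flat is the
# (J*(m+1)) x K flattening of the response array (categories within item)
pattern_loglik <- function(C, resp_flat) {
  C %*% log(pmax(resp_flat, 1e-300))
}

em_one_start <- function(C, counts, J, m, K, max_iter, tol) {
  N <- sum(counts)
  # uniform Dirichlet draws for weights and every response row
  rdirich <- function(n) { g <- stats::rgamma(n, 1); g / sum(g) }
  w <- rdirich(K)
  resp_flat <- matrix(stats::rgamma(J * (m + 1L) * K, 1), J * (m + 1L), K)
  item_of <- rep(seq_len(J), each = m + 1L)
  norm_resp <- function(r) {
    tot <- rowsum(r, item_of)                 # J x K column sums per item
    r / tot[item_of, , drop = FALSE]
  }
  resp_flat <- norm_resp(resp_flat)
  ll_trace <- numeric(max_iter)
  ll_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    A <- pattern_loglik(C, resp_flat)
    A <- sweep(A, 2L, log(pmax(w, 1e-300)), "+")
    amax <- apply(A, 1L, max)
    lse <- amax + log(rowSums(exp(A - amax)))
    ll <- sum(counts * lse)
    ll_trace[it] <- ll
    z <- exp(A - lse)                         # posterior class memberships
    nz <- counts * z                          # weighted by pattern counts
    ck <- colSums(nz)
    w <- ck / N
    resp_flat <- crossprod(C, nz) / rep(pmax(ck, 1e-300),
                                        each = J * (m + 1L))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w,
       response = array(resp_flat, c(m + 1L, J, K)),  # categories, items, K
       loglik = ll_trace[it], loglik_trace = ll_trace[seq_len(it)],
       converged = converged)
}

#' Fit an unconstrained latent class model by EM
#'
#' Multiple random starts (class-conditional response probabilities and
#' weights drawn from uniform Dirichlet distributions); the best start by
#' final log-likelihood wins.  The EM log-likelihood is nondecreasing over
#' iterations; the trace is kept on the returned object.  Label switching
#' needs no treatment downstream: the reliability assembly is invariant to
#' class permutation.
#'
#' @param data an \code{item_scores} object.
#' @param K number of classes (>= 1).
#' @param n_starts number of random starts.
#' @param seed RNG seed (recorded on the model).
#' @param max_iter,tol EM stopping rule: stop when the relative
#'   log-likelihood change drops below \code{tol} or after \code{max_iter}
#'   iterations.
#' @return a \code{\link{latent_class_model}}.
#' @export
fit_lcm <- function(data, K, n_starts = 25, seed = 1, max_iter = 2000,
                    tol = 1e-8) {
  data <- as_item_matrix(data)
  K <- as.integer(K)
  N <- nrow(data); m <- attr(data, "m")
  stopifnot(K >= 1L)
  if (N <= K) stop("need more persons than classes", call. = FALSE)
  cp <- collapse_patterns(data)
  if (K > nrow(cp$patterns))
    warning("K = ", K, " exceeds the number of distinct response patterns (",
            nrow(cp$patterns), "); the model is not identifiable",
            call. = FALSE)
  J <- ncol(data)
  C <- pattern_indicator(cp$patterns, m)
  if (K == 1L) {
    # closed-form MLE: observed category proportions
    resp <- array(0, c(J, m + 1L, 1L))
    for (j in seq_len(J))
      resp[j, , 1L] <- tabulate(data[, j] + 1L, nbins = m + 1L) / N
    resp_flat <- matrix(aperm(resp, c(2L, 1L, 3L)), J * (m + 1L), 1L)
    ll <- sum(cp$counts * pattern_loglik(C, resp_flat))
    return(latent_class_model(1, resp, loglik = ll, n_starts = 0L,
                              seed = seed, converged = TRUE,
                              loglik_trace = ll))
  }
  set.seed(seed)
  best <- NULL
  all_ll <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    fit <- em_one_start(C, cp$counts, J, m, K, max_iter, tol)
    all_ll[s] <- fit$loglik
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!is.finite(best$loglik))
    stop("EM failed in every start (non-finite log-likelihood); ",
         "start log-likelihoods: ", paste(round(all_ll, 2), collapse = ", "),
         call. = FALSE)
  if (!best$converged)
    warning("EM reached max_iter without meeting the tolerance in the ",
            "best start", call. = FALSE)
  mod <- latent_class_model(best$weights, aperm(best$response, c(2L, 1L, 3L)),
                            loglik = best$loglik, n_starts = n_starts,
                            seed = seed, converged = best$converged,
                            loglik_trace = best$loglik_trace)
  mod$start_logliks <- all_ll
  mod
}

#' Number of free parameters and BIC of a latent class model
#' @param model a \code{latent_class_model}.
#' @param N sample size used in the fit.
#' @return scalar BIC.
#' @export
lcm_bic <- function(model, N) {
  npar <- (model$K - 1) + model$K * model$J * model$m
  -2 * model$loglik + npar * log(N)
}

#' Model-implied same-item joint cumulative probabilities (method LCRC)
#'
#' For two independent repetitions of item i within latent classes:
#' \deqn{\tilde\pi_{x(i),y(i')} = \sum_k P(\xi=k) P(X_i \ge x | \xi=k)
#'   P(X_i \ge y | \xi=k).}
#'
#' @param model a \code{latent_class_model}.
#' @param item item index.
#' @return m x m matrix, symmetric, nonincreasing in both directions.
#' @export
lcrc_joint_approx <- function(model, item) {
  stopifnot(inherits(model, "latent_class_model"))
  item <- as.integer(item)
  stopifnot(item >= 1L, item <= model$J)
  m <- model$m
  # cumulative P(Xi >= x | k) for x = 1..m
  cum <- apply(model$response[item, , , drop = FALSE], 3L,
               function(p) rev(cumsum(rev(p)))[-1L])
  cum <- matrix(cum, nrow = m)
  tab <- matrix(0, m, m)
  for (k in seq_len(model$K))
    tab <- tab + model$weights[k] * outer(cum[, k], cum[, k])
  tab
}

#' Item-score reliability implied by a latent class model's own parameters
#'
#' Uses the model-implied marginals and the model-implied item-score
#' variance (no data involved); this is the population reliability of the
#' stated model, and the quantity a perfectly recovered fit should
#' reproduce.
#'
#' @param model a \code{latent_class_model}.
#' @param item item index.
#' @return scalar reliability.
#' @export
lcrc_model_reliability <- function(model, item) {
  tab <- lcrc_joint_approx(model, item)
  m <- model$m
  marg_cat <- matrix(model$response[item, , ],
                     ncol = model$K) %*% model$weights     # P(Xi = x)
  marg_cum <- rev(cumsum(rev(marg_cat)))[-1L]              # P(Xi >= x)
  x <- 0:m
  v <- sum(x^2 * marg_cat) - sum(x * marg_cat)^2
  reliability_from_approximation(tab, marg_cum, v)
}

#' Model-implied marginal cumulative probabilities
#' @param model a \code{latent_class_model}.
#' @param item item index.
#' @return length-m vector of P(Xi >= x), x = 1..m.
#' @export
lcm_marginal <- function(model, item) {
  marg_cat <- matrix(model$response[item, , ], ncol = model$K) %*%
    model$weights
  rev(cumsum(rev(marg_cat)))[-1L]
}

#' Item-score reliability by method LCRC
#'
#' Fits the latent class model (or selects K by BIC over \code{1..k_max}),
#' then per item combines the model-implied same-item joint cumulative
#' probabilities with the sample marginals and the sample item variance
#' (denominator N - 1).
#'
#' @param data an \code{item_scores} object.
#' @param K integer number of classes, or \code{"bic"} to select the K in
#'   \code{1..k_max} minimizing BIC.
#' @param n_starts random EM starts per fitted K.
#' @param seed RNG seed, recorded in the report settings.
#' @param k_max largest K tried under BIC selection.
#' @return a \code{\link{reliability_report}} with method \code{"LCRC"};
#'   the fitted model is attached as attribute \code{"model"}.
#' @export
lcrc_reliability <- function(data, K = "bic", n_starts = 25, seed = 1,
                             k_max = 5) {
  data <- as_item_matrix(data)
  if (identical(K, "bic")) {
    fits <- lapply(seq_len(k_max), function(k)
      fit_lcm(data, k, n_starts = n_starts, seed = seed + k))
    bics <- vapply(fits, lcm_bic, numeric(1L), N = nrow(data))
    model <- fits[[which.min(bics)]]
    k_used <- model$K
  } else {
    model <- fit_lcm(data, as.integer(K), n_starts = n_starts, seed = seed)
    k_used <- as.integer(K)
  }
  tables <- estimate_cumulative_tables(data)
  v <- apply(data, 2L, stats::var)
  est <- vapply(seq_len(ncol(data)), function(i) {
    if (v[i] <= 0) stop("degenerate item ", i, ": zero variance",
                        call. = FALSE)
    reliability_from_approximation(lcrc_joint_approx(model, i),
                                   tables$marginal[i, -1L], v[i])
  }, numeric(1L))
  rep <- reliability_report("LCRC", est,
                            settings = list(K = k_used,
                                            selection = if (identical(K, "bic")) "bic" else "fixed",
                                            n_starts = n_starts, seed = seed),
                            item_labels = colnames(data))
  attr(rep, "model") <- model
  rep
}

#' Simulate data from a latent class model
#'
#' @param model a \code{latent_class_model}.
#' @param N number of persons.
#' @param seed RNG seed.
#' @return an \code{item_scores} object.
#' @export
simulate_lcm <- function(model, N, seed = 1) {
  set.seed(seed)
  k <- sample.int(model$K, N, replace = TRUE, prob = model$weights)
  X <- matrix(0L, N, model$J)
  for (j in seq_len(model$J)) {
    p <- t(model$response[j, , k])            # N x (m+1)
    u <- stats::runif(N)
    X[, j] <- as.integer(rowSums(u > t(apply(p, 1L, cumsum)))[])
  }
  # rowSums counts how many cumulative bins u exceeds -> category index
  item_scores(X, m = model$m)
}
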