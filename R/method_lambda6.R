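#' Inter-item covariance structure for one target item
#'
#' The full J x J inter-item covariance matrix (denominator N - 1) split,
#' for a target item i, into Sigma_ii — the (J-1) x (J-1) covariance matrix
#' of the remaining items — and sigma_i, the vector of covariances of item i
#' with the rest.
#'
#' @param data an \code{item_scores} object, or a J x J covariance matrix.
#' @return object of class \code{"inter_item_cov"} wrapping the full matrix.
#' @export
inter_item_cov <- function(data) {
  S <- if (inherits(data, "item_scores")) stats::cov(unclass(data))
       else as.matrix(data)
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("covariance matrix must be symmetric", call. = FALSE)
  if (is.null(colnames(S))) colnames(S) <- rownames(S) <-
      paste0("V", seq_len(ncol(S)))
  structure(list(cov = S, J = ncol(S)), class = "inter_item_cov")
}

partition_cov <- function(cov, item) {
  S <- cov$cov
  list(Sigma_ii = S[-item, -item, drop = FALSE],
       sigma_i = S[-item, item],
       var_i = S[item, item])
}

#' Guttman's lambda-6 for a single item
#'
#' The squared multiple correlation of item i regressed on the remaining
#' J - 1 items: \eqn{\lambda_{6i} = \sigma_i' \Sigma_{ii}^{-1} \sigma_i /
#' \sigma^2_{X_i}}, i.e. one minus the relative residual variance of that
#' regression.  In practice a lower bound to the item-score reliability.
#'
#' @param cov an \code{"inter_item_cov"} object (or anything accepted by
#'   \code{\link{inter_item_cov}}).
#' @param item target item index.
#' @return scalar lambda-6.
#' @export
lambda6_item <- function(cov, item) {
  if (!inherits(cov, "inter_item_cov")) cov <- inter_item_cov(cov)
  item <- as.integer(item)
  stopifnot(item >= 1L, item <= cov$J)
  p <- partition_cov(cov, item)
  if (p$var_i <= 0)
    stop("degenerate item ", item, ": zero variance", call. = FALSE)
  if (rcond(p$Sigma_ii) < 1e-12) {
    dep <- colnames(p$Sigma_ii)
    stop("Sigma_ii is (near-)singular for item ", item,
         "; collinear items among: ", paste(dep, collapse = ", "),
         call. = FALSE)
  }
  drop(crossprod(p$sigma_i, solve(p$Sigma_ii, p$sigma_i))) / p$var_i
}

#' Item-score reliability by method lambda-6 for every item
#'
#' Besides the direct regression form, every item is also routed through
#' the generic reliability assembly using the equivalent joint-probability
#' approximation
#' \eqn{\tilde\pi^{\lambda6}_{x(i),y(i')} = \sigma_i'\Sigma_{ii}^{-1}\sigma_i
#' / m^2 + \pi_{x(i)}\pi_{y(i)}}; the two routes are the same quantity
#' algebraically and the implementation verifies they agree to near machine
#' precision as an internal consistency check.
#'
#' @param data an \code{item_scores} object.
#' @return a \code{\link{reliability_report}} with method \code{"LAMBDA6"}.
#' @export
lambda6_reliability <- function(data) {
  data <- as_item_matrix(data)
  J <- ncol(data)
  if (J < 2L) stop("method lambda6 needs at least 2 items", call. = FALSE)
  cov <- inter_item_cov(data)
  tables <- estimate_cumulative_tables(data)
  m <- tables$m
  est <- vapply(seq_len(J), function(i) {
    l6 <- lambda6_item(cov, i)
    marg <- tables$marginal[i, -1L]
    approx <- l6 * cov$cov[i, i] / m^2 + outer(marg, marg)
    via_framework <- sum(approx - outer(marg, marg)) / cov$cov[i, i]
    if (abs(via_framework - l6) > 1e-8 * max(1, abs(l6)))
      stop("internal inconsistency: framework route for lambda6 diverged",
           call. = FALSE)
    l6
  }, numeric(1L))
  reliability_report("LAMBDA6", est, settings = list(),
                     item_labels = colnames(data))
}

#' The lambda-6 joint-probability approximation table for one item
#'
#' Exposes the framework embedding directly (entries may fall outside
#' [0, 1]; they are an algebraic device, not probabilities).
#'
#' @param data an \code{item_scores} object.
#' @param item target item.
#' @return m x m matrix.
#' @export
lambda6_joint_approx <- function(data, item) {
  data <- as_item_matrix(data)
  cov <- inter_item_cov(data)
  tables <- estimate_cumulative_tables(data)
  item <- check_item_index(data, item)
  p <- partition_cov(cov, item)
  num <- drop(crossprod(p$sigma_i, solve(p$Sigma_ii, p$sigma_i)))
  marg <- tables$marginal[item, -1L]
  num / tables$m^2 + outer(marg, marg)
}
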