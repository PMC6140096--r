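#' Coefficient alpha
#'
#' Internal consistency of the sum score:
#' \eqn{\alpha = J/(J-1) \, (1 - \sum_i \sigma^2_{X_i} / \sigma^2_X)}.
#' Variances use denominator N - 1.
#'
#' @param data an \code{item_scores} object or plain numeric matrix
#'   (columns = items).
#' @return scalar alpha.
#' @export
coefficient_alpha <- function(data) {
  X <- if (inherits(data, "item_scores")) unclass(data) else as.matrix(data)
  J <- ncol(X)
  if (J < 2L) stop("coefficient alpha needs at least 2 items", call. = FALSE)
  tot_var <- stats::var(rowSums(X))
  if (tot_var <= 0) stop("zero total-score variance", call. = FALSE)
  J / (J - 1) * (1 - sum(apply(X, 2L, stats::var)) / tot_var)
}

#' Criterion specification for method CA
#'
#' Method CA divides the squared item-criterion correlation by the
#' criterion's reliability.  The default criterion for item i is the rest
#' score R(i) = X - Xi, whose reliability is approximated by coefficient
#' alpha of the J - 1 remaining items.  Alternatively an external criterion
#' vector with a user-supplied reliability can be given (the classic
#' single-item use case).
#'
#' @param mode \code{"rest_score"} or \code{"external"}.
#' @param criterion length-N numeric vector (external mode only).
#' @param reliability criterion reliability in (0, 1] (external mode only).
#' @return object of class \code{"criterion_spec"}.
#' @export
criterion_spec <- function(mode = c("rest_score", "external"),
                           criterion = NULL, reliability = NULL) {
  mode <- match.arg(mode)
  if (mode == "external") {
    if (is.null(criterion) || is.null(reliability))
      stop("external mode requires a criterion vector and its reliability",
           call. = FALSE)
    if (!(reliability > 0 && reliability <= 1))
      stop("criterion reliability must lie in (0, 1]", call. = FALSE)
  }
  structure(list(mode = mode, criterion = criterion,
                 reliability = reliability),
            class = "criterion_spec")
}

#' Item-score reliability by the correction for attenuation (method CA)
#'
#' For each item, the squared product-moment correlation of the item score
#' with the criterion, divided by the criterion's reliability.  With the
#' rest-score criterion the reliability used is coefficient alpha of the
#' J - 1 remaining items.  True scores of item and criterion are assumed to
#' correlate perfectly.  Estimates may exceed 1 and are reported unclipped.
#'
#' @param data an \code{item_scores} object.
#' @param criterion a \code{\link{criterion_spec}}; default rest score.
#' @return a \code{\link{reliability_report}} with method \code{"CA"}.
#' @export
ca_reliability <- function(data, criterion = criterion_spec()) {
  data <- as_item_matrix(data)
  J <- ncol(data); N <- nrow(data)
  stopifnot(inherits(criterion, "criterion_spec"))
  if (criterion$mode == "rest_score") {
    if (J < 3L)
      stop("rest-score criterion needs J >= 3 (alpha of the rest requires ",
           ">= 2 items)", call. = FALSE)
    est <- vapply(seq_len(J), function(i) {
      y <- rowSums(data[, -i, drop = FALSE])
      if (stats::var(y) <= 0)
        stop("zero criterion variance for item ", i, call. = FALSE)
      a <- coefficient_alpha(data[, -i, drop = FALSE])
      if (a <= 0)
        stop("alpha of the rest items is not positive for item ", i,
             "; method CA undefined", call. = FALSE)
      stats::cor(data[, i], y)^2 / a
    }, numeric(1L))
    settings <- list(criterion = "rest_score", reliability_source = "alpha")
  } else {
    y <- criterion$criterion
    if (length(y) != N)
      stop("external criterion must have length N = ", N, call. = FALSE)
    if (stats::var(y) <= 0) stop("zero criterion variance", call. = FALSE)
    est <- vapply(seq_len(J), function(i)
      stats::cor(data[, i], y)^2 / criterion$reliability, numeric(1L))
    settings <- list(criterion = "external",
                     reliability_source = criterion$reliability)
  }
  reliability_report("CA", est, settings = settings,
                     item_labels = colnames(data))
}
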