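# Companion item indices: corrected item-rest correlation and the Mokken
# item scalability coefficient Hi.

#' Corrected item-rest correlation
#'
#' Product-moment correlation of the item score with the rest score
#' R(i) = X - Xi.
#'
#' @param data an \code{item_scores} object.
#' @param item item index.
#' @return scalar correlation.
#' @export
item_rest_correlation <- function(data, item) {
  data <- as_item_matrix(data)
  item <- check_item_index(data, item)
  tr <- total_and_rest_scores(data, item)
  if (stats::var(data[, item]) <= 0 || stats::var(tr$rest) <= 0)
    stop("zero variance in item or rest score", call. = FALSE)
  stats::cor(data[, item], tr$rest)
}

# maximum covariance of two integer score vectors attainable given their
# marginal distributions: comonotone rearrangement (sort both ascending)
max_covariance <- function(xi, xj) {
  n <- length(xi)
  (sum(sort(xi) * sort(xj)) - n * mean(xi) * mean(xj)) / (n - 1)
}

#' Mokken item scalability coefficient Hi
#'
#' Ratio of the sum of the item's covariances with the other items to the
#' sum of the maximum covariances attainable given the pairs' marginal
#' distributions.  Hi = 1 only for error-free Guttman patterns; Hi = 0
#' under independence.
#'
#' @param data an \code{item_scores} object.
#' @param item item index.
#' @return scalar Hi.
#' @export
scalability_Hi <- function(data, item) {
  data <- as_item_matrix(data)
  item <- check_item_index(data, item)
  others <- setdiff(seq_len(ncol(data)), item)
  if (!length(others)) stop("Hi needs at least 2 items", call. = FALSE)
  num <- sum(vapply(others, function(j)
    stats::cov(data[, item], data[, j]), numeric(1L)))
  den <- sum(vapply(others, function(j)
    max_covariance(data[, item], data[, j]), numeric(1L)))
  if (den <= 0)
    stop("undefined index: zero maximum covariance (degenerate marginals)",
         call. = FALSE)
  num / den
}

#' Item index report
#'
#' Item-rest correlation and scalability Hi for every item, with the
#' conventional >= .3 threshold flags attached as annotations.
#'
#' @param data an \code{item_scores} object.
#' @param threshold rule-of-thumb cutoff used for the flags.
#' @return data frame with one row per item.
#' @export
item_indices <- function(data, threshold = 0.3) {
  data <- as_item_matrix(data)
  J <- ncol(data)
  irc <- vapply(seq_len(J), function(i) item_rest_correlation(data, i),
                numeric(1L))
  hi <- vapply(seq_len(J), function(i) scalability_Hi(data, i), numeric(1L))
  data.frame(item = colnames(data), mean = colMeans(data),
             item_rest_correlation = irc, scalability_Hi = hi,
             irc_flag = irc >= threshold, Hi_flag = hi >= threshold,
             row.names = NULL)
}
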