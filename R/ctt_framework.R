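#' Sample cumulative probabilities of an item-score matrix
#'
#' For every item i and score x in 1..m the marginal cumulative probability
#' pi_x(i) = P(Xi >= x), and for every pair of distinct items the joint
#' cumulative probability pi_x(i),y(j) = P(Xi >= x, Xj >= y).  Same-item
#' joint probabilities refer to an independent repetition of the item and
#' are unobservable from a single administration; the corresponding slots
#' are \code{NA}.  Item variances use denominator N - 1.
#'
#' @param data an \code{item_scores} object.
#' @return object of class \code{"cumulative_tables"} with fields
#'   \code{marginal} (J x (m+1) matrix, columns x = 0..m),
#'   \code{joint} (m x m x J x J array, \code{NA} on the same-item slices),
#'   \code{item_variances}, \code{m}, \code{J}, \code{item_labels}.
#' @export
estimate_cumulative_tables <- function(data) {
  data <- as_item_matrix(data)
  J <- ncol(data); m <- attr(data, "m"); N <- nrow(data)
  ge <- lapply(seq_len(m), function(x) unclass(data) >= x)  # N x J per step
  marginal <- cbind(1, matrix(vapply(ge, colMeans, numeric(J)), nrow = J))
  dimnames(marginal) <- list(colnames(data), paste0("x", 0:m))
  joint <- array(NA_real_, dim = c(m, m, J, J),
                 dimnames = list(paste0("x", 1:m), paste0("y", 1:m),
                                 colnames(data), colnames(data)))
  for (x in seq_len(m)) for (y in seq_len(m)) {
    # crossprod of indicator matrices gives all pairwise joint counts at once
    cp <- crossprod(ge[[x]], ge[[y]]) / N   # cp[i, j] = P(Xi>=x, Xj>=y)
    diag(cp) <- NA_real_
    joint[x, y, , ] <- cp
  }
  new_cumulative_tables(marginal, joint,
                        item_variances = apply(data, 2L, stats::var))
}

#' Assemble cumulative tables from known probabilities
#'
#' Used for worked examples where the probabilities are given directly
#' rather than estimated from data.  Item variances, when omitted, are the
#' population variances implied by the marginal cumulative probabilities
#' (Var(Xi) = sum_x (2x-1) pi_x(i) - (sum_x pi_x(i))^2).
#'
#' @param marginal J x m matrix of pi_x(i) for x = 1..m (the uninformative
#'   x = 0 column, identically 1, is added automatically), or J x (m+1)
#'   including it.
#' @param joint m x m x J x J array with \code{joint[x, y, i, j]} =
#'   P(Xi >= x, Xj >= y); same-item slices may be \code{NA}.
#' @param item_variances optional length-J vector.
#' @return a \code{"cumulative_tables"} object.
#' @export
as_cumulative_tables <- function(marginal, joint, item_variances = NULL) {
  marginal <- as.matrix(marginal)
  if (!isTRUE(all.equal(unname(marginal[, 1L]), rep(1, nrow(marginal)))))
    marginal <- cbind(1, marginal)
  m <- ncol(marginal) - 1L; J <- nrow(marginal)
  stopifnot(length(dim(joint)) == 4L, all(dim(joint) == c(m, m, J, J)))
  if (is.null(item_variances)) {
    x <- seq_len(m)
    ex  <- marginal[, -1L, drop = FALSE] %*% rep(1, m)
    ex2 <- marginal[, -1L, drop = FALSE] %*% (2 * x - 1)
    item_variances <- as.numeric(ex2 - ex^2)
  }
  new_cumulative_tables(marginal, joint, item_variances)
}

new_cumulative_tables <- function(marginal, joint, item_variances) {
  J <- nrow(marginal); m <- ncol(marginal) - 1L
  labels <- rownames(marginal)
  if (is.null(labels)) labels <- paste0("V", seq_len(J))
  if (any(marginal < -1e-12 | marginal > 1 + 1e-12))
    stop("marginal cumulative probabilities must lie in [0, 1]", call. = FALSE)
  nonmono <- apply(marginal, 1L, function(p) any(diff(p) > 1e-12))
  if (any(nonmono))
    stop("marginal cumulative probabilities must be nonincreasing in x",
         call. = FALSE)
  structure(list(marginal = marginal, joint = joint,
                 item_variances = stats::setNames(item_variances, labels),
                 m = m, J = J, item_labels = labels),
            class = "cumulative_tables")
}

#' @export
print.cumulative_tables <- function(x, digits = 3, ...) {
  cat(sprintf("cumulative_tables: J = %d items, m = %d\n", x$J, x$m))
  cat("marginal cumulative probabilities:\n")
  print(round(x$marginal, digits))
  invisible(x)
}

#' Order the item steps by ascending marginal cumulative probability
#'
#' The Jm item steps (i, x), x = 1..m, are sorted by ascending pi_x(i).
#' Ties are broken deterministically: by item index, then by descending
#' score category (configurable via \code{tie_break}, either
#' \code{"item_desc_score"} or \code{"item_asc_score"}).
#'
#' @param tables a \code{"cumulative_tables"} object.
#' @param tie_break tie-breaking rule.
#' @return data frame with columns \code{item}, \code{x}, \code{pi},
#'   \code{label}, one row per step, in ascending order.
#' @export
order_item_steps <- function(tables, tie_break = c("item_desc_score",
                                                   "item_asc_score")) {
  tie_break <- match.arg(tie_break)
  m <- tables$m; J <- tables$J
  steps <- expand.grid(x = seq_len(m), item = seq_len(J))
  pi <- tables$marginal[cbind(steps$item, steps$x + 1L)]
  ord <- if (tie_break == "item_desc_score")
    order(pi, steps$item, -steps$x) else order(pi, steps$item, steps$x)
  out <- data.frame(item = steps$item[ord], x = steps$x[ord], pi = pi[ord])
  out$label <- sprintf("pi%d(%d)", out$x, out$item)
  out
}

#' Build the ordered P(++) matrix and its P(--) complement
#'
#' The Jm x Jm matrix of joint cumulative probabilities over the ordered
#' item steps.  Cells pairing two steps of the same item are unobservable
#' (\code{NA}); under the double monotonicity model the observable entries
#' are nondecreasing along rows and columns, which is reported as a
#' diagnostic count of violations but never enforced.  The complement holds
#' P(Xi < x, Xj < y) = 1 - pi_x(i) - pi_y(j) + pi_x(i),y(j) over the same
#' ordering, feeding the Molenaar-Sijtsma candidate scheme.
#'
#' @param tables a \code{"cumulative_tables"} object.
#' @param tie_break passed to \code{\link{order_item_steps}}.
#' @return object of class \code{"pplus_matrix"}: \code{order} (the step
#'   data frame), \code{cells}, \code{complement}, \code{marginals} (ordered
#'   pi values), \code{n_monotonicity_violations}.
#' @export
build_pplus <- function(tables, tie_break = "item_desc_score") {
  ord <- order_item_steps(tables, tie_break)
  S <- nrow(ord)
  cells <- matrix(NA_real_, S, S, dimnames = list(ord$label, ord$label))
  for (r in seq_len(S)) for (cc in seq_len(S)) {
    if (ord$item[r] != ord$item[cc])
      cells[r, cc] <- tables$joint[ord$x[r], ord$x[cc],
                                   ord$item[r], ord$item[cc]]
  }
  complement <- 1 - outer(ord$pi, rep(1, S)) - outer(rep(1, S), ord$pi) + cells
  dimnames(complement) <- dimnames(cells)
  viol <- count_monotonicity_violations(cells)
  structure(list(order = ord, cells = cells, complement = complement,
                 marginals = ord$pi, m = tables$m, J = tables$J,
                 n_monotonicity_violations = viol),
            class = "pplus_matrix")
}

# Adjacent observable pairs along rows and columns that decrease (the double
# monotonicity model predicts nondecreasing); diagnostic only.
count_monotonicity_violations <- function(cells, tol = 1e-12) {
  n <- 0L
  S <- nrow(cells)
  for (r in seq_len(S)) {
    v <- cells[r, ]
    obs <- which(!is.na(v))
    if (length(obs) > 1L) n <- n + sum(diff(v[obs]) < -tol)
  }
  for (cc in seq_len(S)) {
    v <- cells[, cc]
    obs <- which(!is.na(v))
    if (length(obs) > 1L) n <- n + sum(diff(v[obs]) < -tol)
  }
  n
}

#' @export
print.pplus_matrix <- function(x, digits = 2, ...) {
  cat(sprintf("P(++) matrix: %d item steps (J = %d, m = %d), %d monotonicity violation(s)\n",
              nrow(x$cells), x$J, x$m, x$n_monotonicity_violations))
  print(round(x$cells, digits), na.print = "NA")
  invisible(x)
}

#' Write the P(++) matrix as a diagnostic CSV
#'
#' Ordered step labels head the rows and columns; unobservable cells are
#' written as \code{NA}.
#'
#' @param pplus a \code{"pplus_matrix"} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_pplus <- function(pplus, path) {
  df <- data.frame(step = rownames(pplus$cells),
                   pi = pplus$marginals, pplus$cells,
                   check.names = FALSE)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Item-score reliability from an approximation of the same-item joint
#' cumulative probabilities
#'
#' Given any approximation of the unobservable table pi_x(i),y(i') the
#' item-score reliability is
#' \deqn{\rho_{ii'} = \sum_{x=1}^m \sum_{y=1}^m
#'   [\tilde\pi_{x(i),y(i')} - \pi_{x(i)} \pi_{y(i)}] / \sigma^2_{X_i}.}
#' The value is returned unclipped; estimates outside [0, 1] are meaningful
#' to the bias analysis and must not be truncated.
#'
#' @param approx m x m matrix of approximated joint cumulative
#'   probabilities.
#' @param marginal length-m vector of pi_x(i), x = 1..m.
#' @param item_variance variance of the item score (must be positive).
#' @return scalar reliability.
#' @export
reliability_from_approximation <- function(approx, marginal, item_variance) {
  approx <- as.matrix(approx)
  m <- length(marginal)
  stopifnot(all(dim(approx) == c(m, m)))
  if (!is.finite(item_variance) || item_variance <= 0)
    stop("degenerate item: item variance must be positive", call. = FALSE)
  if (any(approx < -1e-9 | approx > 1 + 1e-9))
    stop("approximated joint probabilities must lie in [0, 1]", call. = FALSE)
  sum(approx - outer(marginal, marginal)) / item_variance
}
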