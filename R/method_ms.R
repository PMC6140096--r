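# Molenaar-Sijtsma approximation of the unobservable same-item joint
# cumulative probabilities, generalized to polytomous items.
#
# For an unobservable cell (r, c) of the ordered P(++) matrix, the nearest
# observable entry in each of the four directions (above, below, left,
# right — skipping other unobservable cells) supplies two candidate
# estimates: a ratio-scaling of the neighbor within P(++), and the
# analogous scaling within the complement matrix P(--).  Item steps whose
# marginal cumulative probability ties with another step are pooled and the
# tied block is averaged.  The cell value is the mean of the available
# candidates (at most eight), clipped to the interval
# [pi_r * pi_c, min(pi_r, pi_c)].

#' Candidate estimates for one unobservable P(++) cell
#'
#' The candidate-generation core of method MS, isolated so the scheme can
#' be inspected (and, if ever necessary, corrected) in one place.
#'
#' @param P length-S vector of ordered marginal cumulative probabilities.
#' @param PP S x S ordered P(++) matrix with \code{NA} in unobservable
#'   cells (boundary steps already removed).
#' @param r,c cell position (row, column) in the ordered matrix.
#' @return list with \code{estimates} (numeric, the up-to-8 candidate
#'   values), \code{sources} (the neighbor proportions they were derived
#'   from), and \code{value} (mean of estimates, \code{NaN} when none).
#' @export
ms_candidates <- function(P, PP, r, c) {
  S <- length(P)
  tie_r <- which(P == P[r])
  tie_c <- which(P == P[c])
  tied_r <- length(tie_r) > 1L
  tied_c <- length(tie_c) > 1L

  block_mean <- function(rows, cols) {
    v <- PP[rows, cols, drop = FALSE]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }

  if (tied_r && tied_c) {
    # both steps sit in tie sets: average the observable tied block directly
    val <- block_mean(tie_r, tie_c)
    src <- as.numeric(stats::na.omit(as.vector(PP[tie_r, tie_c])))
    return(list(estimates = val[!is.na(val)], sources = src,
                value = if (is.na(val)) NaN else val))
  }

  # nearest observable neighbor index in each direction (NA when absent);
  # when the row (column) step is tied, the search collapses onto the tie
  # set itself
  nearest <- function(idx_seq, get) {
    obs <- idx_seq[!is.na(vapply(idx_seq, get, numeric(1L)))]
    if (length(obs)) obs[1L] else NA_integer_
  }
  col_val <- function(i) PP[i, c]
  row_val <- function(j) PP[r, j]

  if (tied_r) {
    lowerN <- upperN <- r
    lowerPP <- upperPP <- block_mean(tie_r, tie_c)
  } else {
    lowerN <- nearest(seq(r, S), col_val)          # larger marginal side
    upperN <- nearest(rev(seq(1L, r)), col_val)    # smaller marginal side
    lowerPP <- if (is.na(lowerN)) NA_real_ else block_mean(which(P == P[lowerN]), tie_c)
    upperPP <- if (is.na(upperN)) NA_real_ else block_mean(which(P == P[upperN]), tie_c)
  }
  if (tied_c) {
    rightN <- leftN <- c
    rightPP <- leftPP <- block_mean(tie_r, tie_c)
  } else {
    rightN <- nearest(seq(c, S), row_val)
    leftN  <- nearest(rev(seq(1L, c)), row_val)
    rightPP <- if (is.na(rightN)) NA_real_ else block_mean(tie_r, which(P == P[rightN]))
    leftPP  <- if (is.na(leftN))  NA_real_ else block_mean(tie_r, which(P == P[leftN]))
  }

  ratio_pp <- function(nb, nbPP, target_p) {
    if (is.na(nb) || is.na(nbPP)) NA_real_ else nbPP * target_p / P[nb]
  }
  # the last four candidates are the complement-matrix (P(--)) analogues of
  # the first four: scale the neighbor's P(--) entry by the (1-p) ratio and
  # map the result back to the P(++) scale
  est <- c(
    ratio_pp(lowerN, lowerPP, P[r]),
    ratio_pp(rightN, rightPP, P[c]),
    ratio_pp(upperN, upperPP, P[r]),
    ratio_pp(leftN,  leftPP,  P[c]),
    if (is.na(lowerN)) NA_real_ else
      lowerPP * (1 - P[r]) / (1 - P[lowerN]) -
        P[c] * (P[lowerN] - P[r]) / (1 - P[lowerN]),
    if (is.na(rightN)) NA_real_ else
      rightPP * (1 - P[c]) / (1 - P[rightN]) -
        P[r] * (P[rightN] - P[c]) / (1 - P[rightN]),
    if (is.na(upperN)) NA_real_ else
      upperPP * (1 - P[r]) / (1 - P[upperN]) +
        P[c] * (P[r] - P[upperN]) / (1 - P[upperN]),
    if (is.na(leftN)) NA_real_ else
      leftPP * (1 - P[c]) / (1 - P[leftN]) +
        P[r] * (P[c] - P[leftN]) / (1 - P[leftN])
  )
  src <- unique(c(lowerPP, rightPP, upperPP, leftPP))
  src <- src[!is.na(src)]
  est <- est[!is.na(est)]
  list(estimates = est, sources = src,
       value = if (length(est)) mean(est) else NaN)
}

#' Molenaar-Sijtsma approximation of all unobservable cells
#'
#' Fills every unobservable cell of the ordered P(++) matrix.  Item steps
#' with marginal cumulative probability 0 or 1 are excluded from the scheme
#' (their contribution to the reliability numerator is identically zero and
#' their cells are set to the independence value).  A cell for which no
#' candidate exists (pathological tiny inputs) falls back to the
#' independence value with a warning.
#'
#' @param pplus a \code{"pplus_matrix"} from \code{\link{build_pplus}}.
#' @return object of class \code{"ms_approximation"}: \code{filled} (the
#'   ordered matrix with unobservable cells replaced by their estimates),
#'   \code{candidates} (list per filled cell), and the step \code{order}.
#' @export
ms_approximate <- function(pplus) {
  stopifnot(inherits(pplus, "pplus_matrix"))
  if (pplus$J < 2L)
    stop("method MS needs at least 2 items (no cross-item neighbors exist)",
         call. = FALSE)
  ord <- pplus$order
  P_all <- pplus$marginals
  keep <- P_all > 0 & P_all < 1
  P <- P_all[keep]
  PP <- pplus$cells[keep, keep, drop = FALSE]
  S <- length(P)
  sub_index <- which(keep)

  filled_sub <- PP
  cand <- list()
  for (r in seq_len(S)) for (cc in seq_len(S)) {
    if (!is.na(PP[r, cc])) next
    k <- ms_candidates(P, PP, r, cc)
    val <- k$value
    if (is.nan(val)) {
      warning("no MS candidate available for cell (", r, ",", cc,
              "); falling back to the independence value", call. = FALSE)
      val <- P[r] * P[cc]
    }
    val <- min(max(val, P[r] * P[cc]), min(P[r], P[cc]))
    filled_sub[r, cc] <- val
    cand[[paste0(rownames(PP)[r], ",", colnames(PP)[cc])]] <- k
  }

  filled <- pplus$cells
  filled[sub_index, sub_index] <- filled_sub
  # boundary steps: deterministic events, zero numerator contribution
  bnd <- which(!keep)
  for (r in bnd) filled[r, is.na(filled[r, ])] <-
    P_all[r] * P_all[is.na(filled[r, ])]
  for (cc in bnd) filled[is.na(filled[, cc]), cc] <-
    P_all[is.na(filled[, cc])] * P_all[cc]

  structure(list(filled = filled, candidates = cand, order = ord,
                 marginals = P_all, m = pplus$m, J = pplus$J),
            class = "ms_approximation")
}

# m x m same-item table pi~_x(i),y(i') for one item, read off the filled
# ordered matrix
ms_item_table <- function(approx, item) {
  ord <- approx$order
  pos <- order(ord$x[ord$item == item])    # map category x -> ordered row
  rows <- which(ord$item == item)
  rows <- rows[pos]
  approx$filled[rows, rows, drop = FALSE]
}

#' Item-score reliability by method MS
#'
#' Approximates the same-item joint cumulative probabilities with the
#' Molenaar-Sijtsma scheme and feeds them through the reliability assembly
#' formula, per item.  Deterministic.
#'
#' @param data an \code{item_scores} object.
#' @param tie_break tie rule for the item-step ordering, see
#'   \code{\link{order_item_steps}}.
#' @return a \code{\link{reliability_report}} with method \code{"MS"}.
#' @export
ms_reliability <- function(data, tie_break = "item_desc_score") {
  data <- as_item_matrix(data)
  J <- ncol(data)
  if (J < 2L) stop("method MS needs at least 2 items", call. = FALSE)
  v <- apply(data, 2L, stats::var)
  if (any(v <= 0))
    stop("degenerate item(s) with zero variance: ",
         paste(colnames(data)[v <= 0], collapse = ", "), call. = FALSE)
  tables <- estimate_cumulative_tables(data)
  pplus <- build_pplus(tables, tie_break = tie_break)
  approx <- ms_approximate(pplus)
  est <- vapply(seq_len(J), function(i) {
    reliability_from_approximation(ms_item_table(approx, i),
                                   tables$marginal[i, -1L], v[i])
  }, numeric(1L))
  reliability_report("MS", est, settings = list(tie_break = tie_break),
                     item_labels = colnames(data))
}

# Test-score MS reliability (internal; used to validate the approximation
# scheme cellwise against an external reference).  Follows the reference
# convention: population (N-denominator) variance of the total score.
ms_test_reliability <- function(data, tie_break = "item_asc_score") {
  data <- as_item_matrix(data)
  N <- nrow(data)
  tables <- estimate_cumulative_tables(data)
  pplus <- build_pplus(tables, tie_break = tie_break)
  approx <- ms_approximate(pplus)
  P <- approx$marginals
  keep <- P > 0 & P < 1
  filled <- approx$filled[keep, keep]
  P <- P[keep]
  vX <- stats::var(rowSums(data)) * (N - 1) / N
  sum(filled - outer(P, P)) / vX
}
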