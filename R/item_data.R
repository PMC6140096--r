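#' Construct an item-score matrix
#'
#' The universal input of the package: an \code{N} persons by \code{J} items
#' matrix of integer scores in \code{0..m}.  All items share a single maximum
#' category score \code{m}; by default \code{m} is the observed maximum, but
#' it can be declared larger (e.g., when the top category was never used in
#' the sample).
#'
#' Scores are required to start at 0.  A matrix whose minimum exceeds 0 is
#' rejected unless \code{shift_to_zero = TRUE}, in which case the observed
#' minimum is subtracted from every entry first.  Missing values are always
#' rejected: every downstream computation assumes complete data.
#'
#' @param scores integer matrix (or data frame of integer columns),
#'   persons in rows, items in columns.
#' @param m maximum category score; defaults to the observed maximum.
#' @param item_labels character vector of \code{J} item names; defaults to
#'   existing column names or \code{"V1"..}.
#' @param shift_to_zero rebase scores so the observed minimum becomes 0.
#' @return an object of class \code{"item_scores"}: the integer matrix with
#'   attribute \code{m}.
#' @export
item_scores <- function(scores, m = NULL, item_labels = NULL,
                        shift_to_zero = FALSE) {
  if (is.data.frame(scores)) scores <- as.matrix(scores)
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1L)
  if (anyNA(scores)) {
    bad <- which(is.na(scores), arr.ind = TRUE)[1L, ]
    stop("missing value in scores at row ", bad[1L], ", column ", bad[2L],
         "; complete data are required", call. = FALSE)
  }
  if (!is.numeric(scores))
    stop("scores must be numeric (integer-valued)", call. = FALSE)
  if (any(scores != round(scores)))
    stop("scores must be integers", call. = FALSE)
  storage.mode(scores) <- "integer"
  if (any(scores < 0L))
    stop("negative item scores are not allowed", call. = FALSE)
  if (shift_to_zero) scores <- scores - min(scores)
  if (nrow(scores) >= 1L && min(scores) > 0L)
    stop("scores must start at 0 (observed minimum is ", min(scores),
         "); use shift_to_zero = TRUE to rebase", call. = FALSE)
  if (nrow(scores) < 2L) stop("need at least 2 persons", call. = FALSE)
  obs_max <- max(scores)
  if (is.null(m)) m <- max(obs_max, 1L)
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (obs_max > m)
    stop("observed score ", obs_max, " exceeds declared m = ", m,
         call. = FALSE)
  if (is.null(item_labels)) {
    item_labels <- colnames(scores)
    if (is.null(item_labels)) item_labels <- paste0("V", seq_len(ncol(scores)))
  }
  if (length(item_labels) != ncol(scores))
    stop("item_labels must have one entry per item", call. = FALSE)
  colnames(scores) <- item_labels
  structure(scores, m = m, class = c("item_scores", "matrix", "array"))
}

#' @export
print.item_scores <- function(x, ...) {
  cat(sprintf("item_scores: %d persons x %d items, scores 0..%d\n",
              nrow(x), ncol(x), attr(x, "m")))
  if (nrow(x) <= 10L) print(unclass(x)) else {
    print(utils::head(unclass(x), 5L))
    cat("... (", nrow(x) - 5L, " more rows)\n", sep = "")
  }
  invisible(x)
}

#' Number of items, persons and the maximum score of an item-score matrix
#' @param data an \code{item_scores} object.
#' @return integer scalar.
#' @export
n_items <- function(data) ncol(data)

#' @rdname n_items
#' @export
n_persons <- function(data) nrow(data)

#' @rdname n_items
#' @export
max_score <- function(data) attr(data, "m")

as_item_matrix <- function(data) {
  if (!inherits(data, "item_scores"))
    stop("expected an 'item_scores' object; see item_scores()", call. = FALSE)
  data
}

#' Read an item-score matrix from a delimited text file
#'
#' One row per person, one column per item, integer cells, optional single
#' header row with item labels.
#'
#' @param path file path.
#' @param delimiter field delimiter (default comma).
#' @param header logical; first row holds item labels.
#' @param m declared maximum score; default: observed maximum.
#' @param shift_to_zero rebase scores whose minimum exceeds 0.
#' @return an \code{item_scores} object.
#' @export
read_scores <- function(path, delimiter = ",", header = FALSE, m = NULL,
                        shift_to_zero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = header,
                          colClasses = "character", strip.white = TRUE,
                          na.strings = NULL)
  mat <- as.matrix(df)
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat)))
  if (anyNA(num) || any(mat %in% c("NA", "", "NaN"))) {
    bad <- which(is.na(num) | matrix(mat %in% c("NA", "", "NaN"),
                                     nrow = nrow(mat)), arr.ind = TRUE)[1L, ]
    stop("cell at row ", bad[1L], ", column ", bad[2L],
         " ('", mat[bad[1L], bad[2L]], "') does not parse as an integer score",
         call. = FALSE)
  }
  labels <- if (header) colnames(df) else NULL
  item_scores(num, m = m, item_labels = labels, shift_to_zero = shift_to_zero)
}

#' Write an item-score matrix to a delimited text file
#'
#' Inverse of \code{\link{read_scores}}: \code{read_scores(write_scores(x))}
#' reproduces \code{x}.
#'
#' @param data an \code{item_scores} object.
#' @param path output file path.
#' @param delimiter field delimiter.
#' @param header write the item labels as a first row.
#' @return \code{path}, invisibly.
#' @export
write_scores <- function(data, path, delimiter = ",", header = FALSE) {
  data <- as_item_matrix(data)
  utils::write.table(unclass(data), path, sep = delimiter, row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Total scores and rest scores
#'
#' The test score \code{X} is the row sum over items; the rest score
#' \code{R(i) = X - Xi} removes item \code{i}.
#'
#' @param data an \code{item_scores} object.
#' @param item item index in \code{1..J}.
#' @return list with components \code{total} and \code{rest}, each of length
#'   \code{N}.
#' @export
total_and_rest_scores <- function(data, item) {
  data <- as_item_matrix(data)
  item <- check_item_index(data, item)
  X <- rowSums(data)
  list(total = X, rest = X - data[, item])
}

check_item_index <- function(data, item) {
  if (length(item) != 1L || is.na(item) || item < 1L || item > ncol(data))
    stop("item index must be in 1..", ncol(data), call. = FALSE)
  as.integer(item)
}

#' Assemble a reliability report
#'
#' Container returned by every estimation method: the per-item estimates
#' (raw, never clipped to [0, 1]) plus the settings that produced them.
#'
#' @param method one of \code{"MS"}, \code{"LAMBDA6"}, \code{"LCRC"},
#'   \code{"CA"}.
#' @param estimates numeric vector, one value per item.
#' @param settings named list (for stochastic methods it must record the
#'   seed).
#' @param item_labels item names.
#' @return object of class \code{"reliability_report"}.
#' @export
reliability_report <- function(method, estimates, settings = list(),
                               item_labels = NULL) {
  method <- match.arg(method, c("MS", "LAMBDA6", "LCRC", "CA"))
  if (is.null(item_labels)) item_labels <- paste0("V", seq_along(estimates))
  stopifnot(length(item_labels) == length(estimates))
  structure(list(method = method,
                 estimates = stats::setNames(as.numeric(estimates),
                                             item_labels),
                 settings = settings),
            class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat("Item-score reliability, method ", x$method, "\n", sep = "")
  print(round(x$estimates, digits))
  if (length(x$settings))
    cat("settings: ",
        paste(names(x$settings), unlist(lapply(x$settings, format)),
              sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Serialize a reliability report as JSON
#' @param x a \code{reliability_report}.
#' @param path optional output file; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to a file).
#' @export
report_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "reliability_report"))
  obj <- list(method = x$method, settings = x$settings,
              items = names(x$estimates), estimates = unname(x$estimates))
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
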