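# Bias/variability study harness: replicate data sets per condition,
# estimate item-score reliability with each method, pool the differences
# (estimate - population value) across items and replications, and
# summarize median bias, IQR and percentage of outliers.

#' Summarize a vector of estimation differences
#'
#' Median bias, interquartile range and percentage of outliers (values
#' beyond 1.5 IQR from the first and third quartiles).  The quartile
#' convention matters to the outlier count: \code{"tukey"} uses Tukey
#' hinges (the boxplot convention), \code{"linear"} uses
#' linear-interpolation quantiles (type 7).
#'
#' @param differences nonempty numeric vector.
#' @param quartiles quartile convention.
#' @return list with \code{median_bias}, \code{iqr},
#'   \code{percent_outliers}, \code{n}.
#' @export
summarize_differences <- function(differences,
                                  quartiles = c("tukey", "linear")) {
  quartiles <- match.arg(quartiles)
  if (!length(differences)) stop("empty difference vector", call. = FALSE)
  if (anyNA(differences)) stop("differences contain NA", call. = FALSE)
  if (quartiles == "tukey") {
    fn <- stats::fivenum(differences)
    q1 <- fn[2L]; q3 <- fn[4L]
  } else {
    q <- stats::quantile(differences, c(.25, .75), type = 7, names = FALSE)
    q1 <- q[1L]; q3 <- q[2L]
  }
  iqr <- q3 - q1
  out <- differences < q1 - 1.5 * iqr | differences > q3 + 1.5 * iqr
  list(median_bias = stats::median(differences), iqr = iqr,
       percent_outliers = 100 * mean(out), n = length(differences))
}

# deterministic child seeds below 2^31
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647)
}

# per-item stratification labels used in the reporting of the unequal
# discrimination and two-dimensional conditions
item_strata <- function(cond) {
  if (cond$name == "unequal_alpha")
    return(ifelse(cond$alpha[, 1L] >= 1, "high_alpha", "low_alpha"))
  if (cond$name == "two_dim")
    return(paste0("theta", max.col(cond$alpha)))
  rep("all", cond$J)
}

estimate_by_method <- function(data, method, lcrc_settings, seed) {
  switch(method,
         MS = ms_reliability(data)$estimates,
         LAMBDA6 = lambda6_reliability(data)$estimates,
         CA = ca_reliability(data)$estimates,
         LCRC = lcrc_reliability(
           data, K = lcrc_settings$K,
           n_starts = lcrc_settings$n_starts,
           seed = seed, k_max = lcrc_settings$k_max)$estimates,
         stop("unknown method: ", method, call. = FALSE))
}

#' Run the bias/variability study
#'
#' For each condition: the population item-score reliability is computed
#' once by Monte Carlo, then \code{R} data sets are simulated and every
#' method's per-item estimates are reduced to differences
#' (estimate - population value), pooled across items and replications.
#' Per-replication estimation failures are logged and counted, never
#' silently dropped.  The whole study is reproducible from the master
#' seed.
#'
#' @param conditions list of \code{"grm_condition"} objects (or preset
#'   names).
#' @param methods subset of \code{c("MS", "LAMBDA6", "LCRC", "CA")}.
#' @param R replications per condition (default: each condition's own
#'   \code{replications} field).
#' @param seed master seed; per-replication streams are derived from it.
#' @param quartiles quartile convention for the summaries.
#' @param pop_simulees simulees for the population-reliability oracle.
#' @param lcrc_settings list with \code{K} (\code{"bic"} or integer),
#'   \code{n_starts}, \code{k_max}.
#' @return object of class \code{"study_result"}: per (condition, method)
#'   the pooled differences (with item/stratum labels), the summary, the
#'   population reliabilities, and a failure log.
#' @export
run_study <- function(conditions, methods = c("MS", "LAMBDA6", "CA"),
                      R = NULL, seed = 1, quartiles = "tukey",
                      pop_simulees = 1e6,
                      lcrc_settings = list(K = "bic", n_starts = 25,
                                           k_max = 5)) {
  conditions <- lapply(conditions, function(cc)
    if (inherits(cc, "grm_condition")) cc else grm_condition(cc))
  methods <- match.arg(methods, c("MS", "LAMBDA6", "LCRC", "CA"),
                       several.ok = TRUE)
  lcrc_settings <- utils::modifyList(list(K = "bic", n_starts = 25,
                                          k_max = 5), lcrc_settings)
  results <- list()
  failures <- list()
  pop <- list()
  for (ci in seq_along(conditions)) {
    cond <- conditions[[ci]]
    Rc <- if (is.null(R)) cond$replications else R
    pop_rho <- population_item_reliability(
      cond, n_simulees = pop_simulees, seed = child_seed(seed, 1000L + ci))
    pop[[cond$name]] <- pop_rho
    strata <- item_strata(cond)
    diffs <- stats::setNames(
      replicate(length(methods), vector("list", Rc), simplify = FALSE),
      methods)
    for (r in seq_len(Rc)) {
      data <- simulate_grm(cond, seed = child_seed(seed, ci * 100000L + r))
      for (mth in methods) {
        est <- tryCatch(
          estimate_by_method(data, mth, lcrc_settings,
                             seed = child_seed(seed, ci * 100000L + r)),
          error = function(e) e)
        if (inherits(est, "error")) {
          failures[[length(failures) + 1L]] <-
            list(condition = cond$name, method = mth, replication = r,
                 message = conditionMessage(est))
        } else {
          diffs[[mth]][[r]] <- data.frame(
            condition = cond$name, method = mth, replication = r,
            item = seq_len(cond$J), stratum = strata,
            difference = unname(est) - unname(pop_rho))
        }
      }
    }
    for (mth in methods)
      results[[paste(cond$name, mth, sep = ".")]] <-
        do.call(rbind, diffs[[mth]])
  }
  pooled <- do.call(rbind, results)
  rownames(pooled) <- NULL
  summary <- do.call(rbind, lapply(names(results), function(key) {
    d <- results[[key]]
    s <- summarize_differences(d$difference, quartiles = quartiles)
    data.frame(condition = d$condition[1L], method = d$method[1L],
               n = s$n, median_bias = s$median_bias, iqr = s$iqr,
               percent_outliers = s$percent_outliers)
  }))
  structure(list(differences = pooled, summary = summary,
                 population_reliability = pop, failures = failures,
                 seed = seed, quartiles = quartiles),
            class = "study_result")
}

#' @export
print.study_result <- function(x, digits = 3, ...) {
  cat(sprintf("study_result (seed %s, %s quartiles, %d failure(s))\n",
              format(x$seed), x$quartiles, length(x$failures)))
  s <- x$summary
  s[, 4:6] <- round(s[, 4:6], digits)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Write study results to JSON
#'
#' Includes the raw pooled differences so summaries can be recomputed
#' under another quartile convention.
#'
#' @param result a \code{"study_result"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
study_to_json <- function(result, path) {
  obj <- list(seed = result$seed, quartiles = result$quartiles,
              summary = result$summary,
              population_reliability = result$population_reliability,
              differences = result$differences,
              failures = result$failures)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
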