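# Standard-weight vectors are named by "sex|age" cell keys and sum to 1;
# the same weight set is applied to every compared group so standardised
# rates are comparable.
check_std_weights <- function(w) {
  if (!is.numeric(w) || is.null(names(w)) || !length(w))
    stop("std weights must be a named numeric vector", call. = FALSE)
  if (any(w < 0) || anyNA(w))
    stop("std weights must be nonnegative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-8)
    stop("std weights must sum to 1 (got ", format(sum(w)), ")",
         call. = FALSE)
  invisible(w)
}

#' Standard population weights from combined exposure
#'
#' Weight of each sex x age cell is its total person-years across every
#' ethnicity and group of the table, normalised to sum to 1 — the
#' "total population" standard that makes directly standardised rates
#' comparable across all groups of the analysis.
#'
#' @param table A [cohort_table()] (or data frame with `sex`, `age_group`,
#'   `person_years`).
#' @return Named numeric vector of weights keyed `"sex|age"`, summing
#'   to 1.
#' @export
standard_weights_from <- function(table) {
  df <- as.data.frame(table)
  if (!nrow(df)) stop("empty table", call. = FALSE)
  cell <- paste(df$sex, df$age_group, sep = "|")
  tot <- tapply(df$person_years, cell, sum)
  if (sum(tot) <= 0) stop("no exposure to weight by", call. = FALSE)
  w <- as.numeric(tot) / sum(tot)
  names(w) <- names(tot)
  check_std_weights(w)
  w
}

#' Directly standardise one group's rate draws
#'
#' For each posterior draw, the standardised rate is the weighted sum of
#' the group's sex x age cell rates under the shared standard weights —
#' direct standardisation applied draw-wise, so the result is itself a
#' posterior sample.
#'
#' @param rate_draws Draws x cells matrix of one group's stratum rate
#'   draws, with column names `"sex|age"` matching the weight cells.
#' @param weights Standard weights (see [standard_weights_from()]).
#' @return Numeric vector of standardised-rate draws (length = number of
#'   draws).
#' @export
direct_standardise <- function(rate_draws, weights) {
  check_std_weights(weights)
  rate_draws <- as.matrix(rate_draws)
  cells <- colnames(rate_draws)
  if (is.null(cells)) stop("rate_draws needs cell column names", call. = FALSE)
  miss <- setdiff(names(weights)[weights > 0], cells)
  if (length(miss))
    stop("no rate draws for weight cell(s): ",
         paste(miss, collapse = "; "), call. = FALSE)
  w <- weights[cells]
  w[is.na(w)] <- 0
  drop(rate_draws %*% w)
}

#' Standardised-rate draws for every group of a fit
#'
#' @param fit An [fit_hb()] result for one ethnicity x cause block.
#' @param weights Standard weights shared across groups.
#' @param per Rate scale (default per 100,000 person-years).
#' @return Draws x groups matrix, columns in the design's display order.
#' @export
standardised_rate_draws <- function(fit, weights, per = 1e5) {
  stopifnot(inherits(fit, "hb_fit"))
  rates <- posterior_rates(fit, per)
  strata <- fit$strata
  groups <- design_groups(fit$design)
  out <- sapply(groups, function(g) {
    cols <- which(strata$group == g)
    if (!length(cols)) stop("no strata for group ", g, call. = FALSE)
    sub <- rates[, cols, drop = FALSE]
    colnames(sub) <- paste(strata$sex[cols], strata$age_group[cols],
                           sep = "|")
    direct_standardise(sub, weights)
  })
  colnames(out) <- groups
  out
}

#' Rate-ratio draws
#'
#' Elementwise ratio of two standardised-rate posterior samples, computed
#' per draw and then summarised (never as a ratio of summaries).  Draws
#' from one fitted model share a joint posterior and are paired by index;
#' for groups from separate fits the samples are independent, and
#' `pairing = "independent"` breaks any index alignment by a seeded
#' permutation of the denominator.
#'
#' @param numerator,denominator Numeric draw vectors of equal length;
#'   denominators must be positive.
#' @param pairing `"index"` (default, joint posterior) or
#'   `"independent"`.
#' @param seed Seed for the permutation under `"independent"` pairing.
#' @return Vector of ratio draws.
#' @export
rate_ratio_draws <- function(numerator, denominator,
                             pairing = c("index", "independent"),
                             seed = 1L) {
  pairing <- match.arg(pairing)
  if (length(numerator) != length(denominator))
    stop("numerator and denominator draw counts differ", call. = FALSE)
  if (any(denominator <= 0))
    stop("nonpositive denominator draw(s)", call. = FALSE)
  if (pairing == "independent")
    denominator <- with_seed(seed, sample(denominator))
  numerator / denominator
}

#' Median and 95% credible interval of a draw vector
#'
#' Sample median as the estimate of centrality and the 2.5th/97.5th
#' percentiles as the credible interval, with percentiles computed by
#' linear interpolation between order statistics (type-7 quantiles).
#'
#' @param draws Numeric vector of at least 2 posterior draws.
#' @return Named vector `median`, `lo95`, `hi95`.
#' @export
summarise_draws <- function(draws) {
  if (!is.numeric(draws) || length(draws) < 2L || anyNA(draws))
    stop("need at least 2 finite draws", call. = FALSE)
  q <- stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(median = q[1L], lo95 = q[2L], hi95 = q[3L])
}

#' Tail-probability significance of a rate ratio
#'
#' A difference is called significant when fewer than 10% of posterior
#' rate-ratio draws lie on one side of 1, i.e. when
#' \eqn{\min(p^+, 1 - p^+) < 0.10} with \eqn{p^+ = \Pr(RR > 1)}.  Draws
#' exactly equal to 1 count as not-greater.
#'
#' @param draws Numeric vector of at least 2 rate-ratio draws.
#' @param threshold Tail threshold (default 0.10).
#' @return List with `pr_gt_1` and logical `significant`.
#' @export
significance <- function(draws, threshold = 0.10) {
  if (!is.numeric(draws) || length(draws) < 2L || anyNA(draws))
    stop("need at least 2 finite draws", call. = FALSE)
  p <- mean(draws > 1)
  list(pr_gt_1 = p, significant = min(p, 1 - p) < threshold)
}

#' Summarise standardised rates and rate ratios of a set of fits
#'
#' Builds the publication summary of one analysis: per ethnicity and
#' group, the median standardised rate with 95% CI; within each ethnicity,
#' group-vs-reference rate ratios (overseas- vs native-born, or each
#' duration-of-residence group vs the longest resident); and within each
#' group, ethnicity ratios against the reference ethnicity.  Ratios within
#' one fitted model are paired by draw index; ratios across ethnicities
#' come from separate fits and use the configured pairing.
#'
#' @param fits Named list of `hb_fit` objects from [fit_hb_blocks()]
#'   (one cause).
#' @param weights Shared standard weights.
#' @param per Rate scale.
#' @param ref_ethnicity Reference ethnicity for cross-ethnicity ratios
#'   (default: first block's).
#' @param cross_pairing Pairing rule for cross-ethnicity ratios (see
#'   [rate_ratio_draws()]).
#' @return Data frame with columns `cause`, `ethnicity`, `group`,
#'   `comparison` (`"rate"`, `"vs_ref_group"`, `"vs_ref_ethnicity"`),
#'   `median`, `lo95`, `hi95`, `pr_gt_1`, `significant`.
#' @export
summarise_standardised <- function(fits, weights, per = 1e5,
                                   ref_ethnicity = NULL,
                                   cross_pairing = "independent") {
  stopifnot(is.list(fits), length(fits) >= 1L)
  std <- lapply(fits, standardised_rate_draws, weights = weights, per = per)
  eths <- vapply(fits, function(f) f$strata$ethnicity[1L], character(1))
  cause <- fits[[1L]]$strata$cause[1L]
  design <- fits[[1L]]$design
  groups <- design_groups(design)
  ref_grp <- design_ref_group(design)
  if (is.null(ref_ethnicity)) ref_ethnicity <- eths[1L]
  if (!ref_ethnicity %in% eths)
    stop("reference ethnicity ", ref_ethnicity, " not among the fits",
         call. = FALSE)

  rows <- list()
  add <- function(eth, grp, comparison, draws, ratio = FALSE) {
    s <- summarise_draws(draws)
    sig <- if (ratio) significance(draws) else
      list(pr_gt_1 = NA_real_, significant = NA)
    rows[[length(rows) + 1L]] <<- data.frame(
      cause = cause, ethnicity = eth, group = grp, comparison = comparison,
      median = unname(s["median"]), lo95 = unname(s["lo95"]),
      hi95 = unname(s["hi95"]), pr_gt_1 = sig$pr_gt_1,
      significant = sig$significant, stringsAsFactors = FALSE)
  }
  for (i in seq_along(fits)) {
    eth <- eths[i]
    for (g in groups) add(eth, g, "rate", std[[i]][, g])
    for (g in setdiff(groups, ref_grp))                 # joint posterior
      add(eth, g, "vs_ref_group",
          rate_ratio_draws(std[[i]][, g], std[[i]][, ref_grp]),
          ratio = TRUE)
  }
  ref_i <- match(ref_ethnicity, eths)
  for (i in seq_along(fits)) {
    if (i == ref_i) next
    for (g in groups)                                   # separate fits
      add(eths[i], g, "vs_ref_ethnicity",
          rate_ratio_draws(std[[i]][, g], std[[ref_i]][, g],
                           pairing = cross_pairing,
                           seed = fits[[i]]$mcmc$seed), ratio = TRUE)
  }
  do.call(rbind, rows)
}

#' Write a standardised summary to CSV
#'
#' @param summary Data frame from [summarise_standardised()].
#' @param path Output path.
#' @export
write_summary <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
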