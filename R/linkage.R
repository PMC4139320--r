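#' Stratum-level linkage-bias weight
#'
#' In a probabilistically linked census-mortality cohort not every eligible
#' death record links to a census record; analyses of linked deaths alone
#' would understate mortality.  The correction weight for a stratum is the
#' ratio of eligible to successfully linked deaths, applied to each linked
#' death so the weighted count represents all eligible deaths (e.g. 20 of
#' 30 eligible deaths linked gives each linked record a weight of
#' 30/20 = 1.5).
#'
#' @param eligible_deaths,linked_deaths Nonnegative integer vectors with
#'   `linked_deaths <= eligible_deaths`.
#' @return Numeric vector of weights, always `>= 1` when linkage is
#'   incomplete.  Strata with `eligible_deaths == 0` get weight 1 (nothing
#'   to weight).
#' @export
#' @examples
#' linkage_weight(30, 20)  # 1.5
linkage_weight <- function(eligible_deaths, linked_deaths) {
  check_count <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != round(x)))
      stop(nm, " must be nonnegative integers", call. = FALSE)
  }
  check_count(eligible_deaths, "eligible_deaths")
  check_count(linked_deaths, "linked_deaths")
  if (any(linked_deaths > eligible_deaths))
    stop("linked_deaths exceeds eligible_deaths", call. = FALSE)
  unlinked <- linked_deaths == 0 & eligible_deaths > 0
  if (any(unlinked))
    stop("unweightable stratum: eligible deaths but none linked ",
         "(pool strata before weighting); offending index(es): ",
         paste(which(unlinked), collapse = ", "), call. = FALSE)
  ifelse(eligible_deaths == 0, 1, eligible_deaths / linked_deaths)
}

#' Linkage-weighted death count
#'
#' @param linked_deaths Nonnegative count of linked deaths.
#' @param weight Linkage weight, `>= 1` (see [linkage_weight()]).
#' @return `linked_deaths * weight`; equals the eligible count when the
#'   weight is the stratum's eligible/linked ratio.
#' @export
weighted_deaths <- function(linked_deaths, weight) {
  if (!is.numeric(linked_deaths) || anyNA(linked_deaths) ||
      any(linked_deaths < 0))
    stop("linked_deaths must be nonnegative", call. = FALSE)
  if (!is.numeric(weight) || anyNA(weight) || any(weight < 0))
    stop("weight must be nonnegative", call. = FALSE)
  if (any(weight < 1))
    stop("linkage weights are >= 1 by construction", call. = FALSE)
  linked_deaths * weight
}

# Broad age bands used when pooling linkage strata, mirroring the pooled
# weighting strata of linked census-mortality studies (e.g. "males aged
# 45-64").
BROAD_AGE <- c("25-29" = "25-44", "30-34" = "25-44", "35-39" = "25-44",
               "40-44" = "25-44", "45-49" = "45-64", "50-54" = "45-64",
               "55-59" = "45-64", "60-64" = "45-64", "65-69" = "65-74",
               "70-74" = "65-74")

#' Apply linkage weights to a cohort table
#'
#' Computes eligible/linked weights and replaces the `deaths` column with
#' the weighted count, so downstream rate models represent all eligible
#' deaths.  With `pooling = "stratum"` each analysis stratum gets its own
#' weight; strata with eligible deaths but no linked deaths then raise an
#' error naming the cells, since they cannot be weighted.  With
#' `pooling = "broad_age"` weights are computed on pooled linkage strata
#' (ethnicity x group x sex x broad age band 25--44 / 45--64 / 65--74) and
#' applied to every member stratum — the form linkage weights take in
#' practice, and robust to sparse cells.
#'
#' @param table A [cohort_table()] carrying `eligible_deaths` and
#'   `linked_deaths`.
#' @param pooling `"stratum"` or `"broad_age"`.
#' @return The table with `deaths` replaced by the weighted count.
#' @export
apply_linkage_weights <- function(table,
                                  pooling = c("stratum", "broad_age")) {
  stopifnot(inherits(table, "cohort_table"))
  pooling <- match.arg(pooling)
  if (anyNA(table$eligible_deaths) || anyNA(table$linked_deaths))
    stop("eligible_deaths/linked_deaths required to apply linkage weights",
         call. = FALSE)
  if (pooling == "stratum") {
    unlinked <- table$linked_deaths == 0 & table$eligible_deaths > 0
    if (any(unlinked))
      stop("unweightable stratum (eligible deaths, none linked): ",
           paste(cell_key(table)[unlinked], collapse = "; "),
           "; pool strata (pooling = \"broad_age\") or merge cells",
           call. = FALSE)
    w <- linkage_weight(table$eligible_deaths, table$linked_deaths)
  } else {
    # Cascade of pooling levels, finest first; a stratum uses the finest
    # pool in which any of its deaths linked, so weights stay defined in
    # sparse cells without silently inflating counts.
    levels <- list(
      paste(table$ethnicity, table$group, table$sex,
            BROAD_AGE[table$age_group], sep = "|"),
      paste(table$ethnicity, table$group, sep = "|"),
      rep("all", nrow(table)))
    w <- rep(NA_real_, nrow(table))
    w[table$eligible_deaths == 0] <- 1
    for (pool in levels) {
      elig <- tapply(table$eligible_deaths, pool, sum)
      link <- tapply(table$linked_deaths, pool, sum)
      ok <- is.na(w) & unname(link[pool]) > 0
      w[ok] <- unname((elig / pmax(link, 1))[pool])[ok]
      if (!anyNA(w)) break
    }
    if (anyNA(w))
      stop("unweightable table: eligible deaths but none linked anywhere",
           call. = FALSE)
  }
  table$deaths <- weighted_deaths(table$linked_deaths, w)
  cohort_table(as.data.frame(table), design = attr(table, "design"))
}
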