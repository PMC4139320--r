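# Ten five-year age bands spanning 25-74; index order = age order.
AGE_LABELS <- c("25-29", "30-34", "35-39", "40-44", "45-49",
                "50-54", "55-59", "60-64", "65-69", "70-74")
AGE_CENTRE <- "45-49"

SEX_LEVELS <- c("M", "F")

# Canonical group levels per design, in display order, and the reference
# level used for regression dummies and rate-ratio denominators.
DESIGN_GROUPS <- list(
  nativity = c("NZB", "OSB"),
  dor      = c("0-9", "10-24", "25+")
)
DESIGN_REF <- c(nativity = "NZB", dor = "25+")

COHORT_COLUMNS <- c("ethnicity", "cause", "sex", "age_group", "group",
                    "person_years", "deaths", "eligible_deaths",
                    "linked_deaths")

#' Age bands of the stratification
#'
#' The ten five-year age bands (25--29 through 70--74) used to stratify the
#' cohort, in ascending age order.
#'
#' @return Character vector of the ten age-band labels.
#' @export
age_groups <- function() AGE_LABELS

#' Group levels of a stratification design
#'
#' @param design `"nativity"` (overseas-born vs New Zealand-born, 2 groups)
#'   or `"dor"` (duration of residence 0--9 / 10--24 / 25+ years, 3 groups).
#' @return Character vector of group labels in display order.
#' @export
design_groups <- function(design) {
  design <- match.arg(design, names(DESIGN_GROUPS))
  DESIGN_GROUPS[[design]]
}

#' Reference group of a design
#'
#' The denominator group for within-ethnicity rate ratios: the native-born
#' for the nativity design, the longest-resident (25+ years) group for the
#' duration-of-residence design.
#'
#' @inheritParams design_groups
#' @return A single group label.
#' @export
design_ref_group <- function(design) {
  design <- match.arg(design, names(DESIGN_GROUPS))
  unname(DESIGN_REF[design])
}

#' Centred, scaled age score of an age band
#'
#' Maps each five-year band to an integer score centred at the 45--49 band,
#' so one unit of scaled age corresponds to five years of actual age.  The
#' ten bands map to the consecutive integers -4 through +5.
#'
#' @param age_group Character vector of age-band labels (see [age_groups()]).
#' @return Integer vector of scaled-age scores.
#' @export
#' @examples
#' scale_age("45-49")  # 0
#' scale_age("25-29")  # -4
scale_age <- function(age_group) {
  idx <- match(age_group, AGE_LABELS)
  if (anyNA(idx)) {
    bad <- unique(age_group[is.na(idx)])
    stop("unknown age-group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx - match(AGE_CENTRE, AGE_LABELS)
}

# Knot positions of the age spline on the scaled-age axis: the 35-39 and
# 55-59 bands.
SPLINE_KNOTS <- c(-2L, 2L)

#' Linear age-spline basis
#'
#' Truncated-power (hinge) basis for a piecewise-linear age effect with
#' knots at the 35--39 and 55--59 bands (scaled-age positions -2 and +2):
#' columns \eqn{a}, \eqn{(a - k_1)_+}, \eqn{(a - k_2)_+}.  Continuous and
#' piecewise-linear in the scaled age \eqn{a}.
#'
#' @param a Numeric vector of scaled-age scores (see [scale_age()]).
#' @param knots Length-2 numeric vector of knot positions on the scaled-age
#'   axis.
#' @return Numeric matrix with one row per element of `a` and columns
#'   `age`, `hinge1`, `hinge2`.
#' @export
spline_basis <- function(a, knots = SPLINE_KNOTS) {
  if (!is.numeric(a) || anyNA(a) || any(!is.finite(a)))
    stop("scaled age must be finite numeric", call. = FALSE)
  stopifnot(length(knots) == 2L)
  cbind(age = as.numeric(a),
        hinge1 = pmax(a - knots[1L], 0),
        hinge2 = pmax(a - knots[2L], 0))
}

# Run `expr` under a temporary RNG state seeded with `seed`; global RNG
# state is untouched.  With seed = NULL the global stream is used.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random rounding to base 3 (RR3)
#'
#' Unbiased random rounding of counts to multiples of three, the
#' disclosure-control rule applied to published count tables: multiples of
#' three are returned unchanged; other counts move to the nearest multiple
#' with probability 2/3 and to the second-nearest with probability 1/3, so
#' the expected output equals the input and the output is always within 2
#' of it.
#'
#' @param count Vector of nonnegative integer counts.
#' @param seed Optional integer; when supplied the rounding is reproducible
#'   and the global RNG state is left untouched.
#' @return Integer vector of rounded counts (multiples of 3).
#' @export
rr3 <- function(count, seed = NULL) {
  if (!is.numeric(count) || anyNA(count) || any(count < 0) ||
      any(count != round(count)))
    stop("counts must be nonnegative integers", call. = FALSE)
  count <- as.integer(round(count))
  with_seed(seed, {
    rem <- count %% 3L
    down <- count - rem
    # rem 1: nearest is down; rem 2: nearest is up
    nearest <- ifelse(rem == 1L, down, down + 3L)
    second  <- ifelse(rem == 1L, down + 3L, down)
    pick_nearest <- stats::runif(length(count)) < 2 / 3
    out <- ifelse(rem == 0L, count, ifelse(pick_nearest, nearest, second))
    as.integer(out)
  })
}

#' Suppress small confidentialised counts
#'
#' Applies the minimum publishable cell size of 6 to counts already rounded
#' to base 3: a nonzero count below 6 (i.e. the value 3) is replaced by
#' `NA`, the suppression marker; zero cells are structurally empty and pass
#' through, as do counts of 6 or more.  Suppressed cells are serialised as
#' the literal token `"S"` by [format_confidential()].
#'
#' @param count Vector of counts that are multiples of 3 (post-RR3).
#' @return Numeric vector with `NA` in suppressed cells.
#' @export
suppress_small <- function(count) {
  if (!is.numeric(count) || anyNA(count) || any(count < 0) ||
      any(count %% 3 != 0))
    stop("counts must be nonnegative multiples of 3 (apply rr3() first)",
         call. = FALSE)
  ifelse(count > 0 & count < 6, NA_real_, count)
}

#' Format confidentialised counts for publication
#'
#' @param count Vector from [suppress_small()]; `NA` marks suppression.
#' @return Character vector with suppressed cells rendered as `"S"`.
#' @export
format_confidential <- function(count) {
  ifelse(is.na(count), "S", format(count, trim = TRUE, scientific = FALSE))
}

#' Construct a validated cohort table
#'
#' A cohort table holds one row per stratum of the cross-classification
#' ethnicity x cause x sex x age band x group, with weighted person-years
#' at risk and (possibly linkage-weighted) deaths, plus optional raw
#' eligible/linked death counts.  Validation enforces completeness of the
#' sex x age x group grid within every ethnicity x cause block (40 cells
#' for the nativity design, 60 for duration of residence) and the count
#' invariants.
#'
#' @param records Data frame with columns `ethnicity`, `cause`, `sex`
#'   (`"M"`/`"F"`), `age_group`, `group`, `person_years`, `deaths`, and
#'   optionally `eligible_deaths`, `linked_deaths`.
#' @param design `"nativity"`, `"dor"`, or `NULL` to infer from the group
#'   labels present.
#' @return A `cohort_table`: the validated data frame with a `design`
#'   attribute.
#' @export
cohort_table <- function(records, design = NULL) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- setdiff(COHORT_COLUMNS, c("eligible_deaths", "linked_deaths"))
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("cohort table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("eligible_deaths", "linked_deaths"))
    if (!col %in% names(records)) records[[col]] <- NA_real_
  records <- records[, COHORT_COLUMNS]

  if (is.null(design)) {
    groups <- unique(records$group)
    hit <- vapply(DESIGN_GROUPS, function(g) all(groups %in% g), logical(1))
    if (!any(hit))
      stop("cannot infer design: unknown group label(s) ",
           paste(setdiff(groups, unlist(DESIGN_GROUPS)), collapse = ", "),
           call. = FALSE)
    design <- names(DESIGN_GROUPS)[which(hit)[1L]]
  }
  design <- match.arg(design, names(DESIGN_GROUPS))

  out <- validate_cohort(records, design)
  structure(out, design = design, class = c("cohort_table", "data.frame"))
}

# Validation worker: count invariants, duplicate cells, grid completeness.
validate_cohort <- function(records, design) {
  groups <- DESIGN_GROUPS[[design]]

  bad_sex <- !records$sex %in% SEX_LEVELS
  if (any(bad_sex))
    stop("row(s) ", paste(which(bad_sex), collapse = ", "),
         ": sex must be one of ", paste(SEX_LEVELS, collapse = "/"),
         call. = FALSE)
  scale_age(records$age_group)  # errors on unknown labels
  bad_grp <- !records$group %in% groups
  if (any(bad_grp))
    stop("row(s) ", paste(which(bad_grp), collapse = ", "),
         ": group not valid for the ", design, " design: ",
         paste(unique(records$group[bad_grp]), collapse = ", "),
         call. = FALSE)

  num_ok <- function(x) is.numeric(x) & !is.na(x) & x >= 0
  if (!all(num_ok(records$person_years)))
    stop("row(s) ", paste(which(!num_ok(records$person_years)), collapse = ", "),
         ": person_years must be nonnegative", call. = FALSE)
  if (!all(num_ok(records$deaths)))
    stop("row(s) ", paste(which(!num_ok(records$deaths)), collapse = ", "),
         ": deaths must be nonnegative", call. = FALSE)
  bad_zero <- records$person_years == 0 & records$deaths > 0
  if (any(bad_zero))
    stop("row(s) ", paste(which(bad_zero), collapse = ", "),
         ": deaths must be 0 where person_years is 0", call. = FALSE)
  both <- !is.na(records$eligible_deaths) & !is.na(records$linked_deaths)
  bad_link <- both & records$linked_deaths > records$eligible_deaths
  if (any(bad_link))
    stop("row(s) ", paste(which(bad_link), collapse = ", "),
         ": linked_deaths exceeds eligible_deaths", call. = FALSE)

  key <- cell_key(records)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate stratum cell(s): ", paste(dup, collapse = "; "),
         call. = FALSE)
  }
  # grid completeness within each ethnicity x cause block
  for (eth in unique(records$ethnicity)) for (cs in unique(records$cause)) {
    block <- records$ethnicity == eth & records$cause == cs
    if (!any(block)) next
    want <- expand.grid(sex = SEX_LEVELS, age_group = AGE_LABELS,
                        group = groups, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    want_key <- paste(want$sex, want$age_group, want$group, sep = "|")
    have_key <- paste(records$sex[block], records$age_group[block],
                      records$group[block], sep = "|")
    miss <- setdiff(want_key, have_key)
    if (length(miss))
      stop("incomplete grid for ethnicity ", eth, ", cause ", cs,
           ": missing cell(s) ", paste(miss, collapse = "; "),
           call. = FALSE)
  }
  rownames(records) <- NULL
  records
}

# Unique key of a stratum cell.
cell_key <- function(records) {
  paste(records$ethnicity, records$cause, records$sex, records$age_group,
        records$group, sep = "|")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> design =", attr(x, "design"),
      "|", nrow(x), "strata |",
      length(unique(x$ethnicity)), "ethnicities x",
      length(unique(x$cause)), "cause(s)\n")
  cat(sprintf("  person-years %.0f, deaths %.1f\n",
              sum(x$person_years), sum(x$deaths)))
  invisible(x)
}

#' Read a cohort table from CSV
#'
#' @param path Path to a comma-delimited UTF-8 file with a header row
#'   naming the cohort-table columns.
#' @inheritParams cohort_table
#' @return A validated [cohort_table()].
#' @export
read_cohort <- function(path, design = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (col in intersect(c("person_years", "deaths", "eligible_deaths",
                          "linked_deaths"), names(df)))
    df[[col]] <- as.numeric(df[[col]])
  cohort_table(df, design = design)
}

#' Write a cohort table to CSV
#'
#' Numeric columns are written with full precision so that
#' read -> write -> read round-trips to an identical table.
#'
#' @param table A [cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  out <- as.data.frame(table)
  for (col in c("person_years", "deaths", "eligible_deaths", "linked_deaths"))
    out[[col]] <- vapply(out[[col]], function(v)
      if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE),
      character(1))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
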