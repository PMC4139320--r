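#' Cause-specific baseline log-rates for simulated runs
#'
#' Baselines are set so standardised all-cause rates land in the low
#' hundreds per 100,000 person-years with cancer and cardiovascular
#' baselines at roughly one third of the all-cause level, an Indian
#' cardiovascular excess (~2.2x) and an Indian cancer deficit (~0.7x)
#' relative to the Chinese baseline.
#'
#' @param cause `"all-cause"`, `"cancer"` or `"CVD"`.
#' @return Named vector of per-ethnicity baseline log-rates, or `NULL`
#'   for an unknown cause.
#' @export
default_cause_beta0 <- function(cause) {
  switch(cause,
         "all-cause" = DEFAULT_BETA0,
         "cancer" = c("Chinese" = -7.84, "Indian" = -7.84 + log(0.69),
                      "Other Asian" = -7.84 + log(0.99)),
         "CVD" = c("Chinese" = -8.03, "Indian" = -8.03 + log(2.22),
                   "Other Asian" = -8.03 + log(1.06)),
         NULL)
}

#' Pipeline configuration
#'
#' @param design Stratification design, `"nativity"` or `"dor"`
#'   (required).
#' @param causes Character vector of causes to analyse; each default cause
#'   (`"all-cause"`, `"cancer"`, `"CVD"`) has its own simulated baseline.
#' @param ethnicities Ethnic groups; the first is the reference for
#'   cross-ethnicity rate ratios.
#' @param seed Master seed; cohort generation, MCMC chains and
#'   disclosure-control rounding all derive their seeds from it.
#' @param input Optional path to a cohort CSV to analyse instead of
#'   simulating (its causes override `causes`).
#' @param generator Named list of [generator_config()] overrides applied
#'   to every simulated cause.
#' @param mcmc Named list of [mcmc_config()] overrides.
#' @param per Rate scale (default per 100,000 person-years).
#' @param outdir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(design, causes = c("all-cause", "cancer", "CVD"),
                            ethnicities = c("Chinese", "Indian",
                                            "Other Asian"),
                            seed = 1L, input = NULL, generator = list(),
                            mcmc = list(), per = 1e5, outdir = "results") {
  if (missing(design) || is.null(design))
    stop("configuration error: design (nativity or dor) is required",
         call. = FALSE)
  design <- match.arg(design, names(DESIGN_GROUPS))
  structure(list(design = design, causes = causes,
                 ethnicities = ethnicities, seed = as.integer(seed),
                 input = input, generator = generator, mcmc = mcmc,
                 per = per, outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path (`.yml`/`.yaml`/`.json`).
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw$design))
    stop("configuration error: design (nativity or dor) is required",
         call. = FALSE)
  raw$causes <- unlist(raw$causes)
  raw$ethnicities <- unlist(raw$ethnicities)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or ingest) -> confidentialised count export ->
#' linkage weighting -> hierarchical Bayesian fit per ethnicity x cause ->
#' draw-wise direct standardisation -> rate-ratio summaries -> rendered
#' rate table, writing all outputs plus a JSON manifest (seeds, versions,
#' convergence diagnostics, dropped strata) to the output directory.
#' Identical configuration and seed give byte-identical CSV outputs.
#'
#' @param config A [pipeline_config()], or a path to one.
#' @param quiet Suppress stage messages.
#' @return Invisibly, a list with the summaries, rendered table, fits and
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[hbmort] ", ...)
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  mcmc_base <- do.call(mcmc_config, c(config$mcmc,
                                      if (is.null(config$mcmc$seed))
                                        list(seed = config$seed)))

  # --- stage: cohorts ------------------------------------------------
  cohorts <- list()
  if (!is.null(config$input)) {
    say("ingest: ", config$input)
    tab <- read_cohort(config$input, design = config$design)
    for (cs in unique(tab$cause))
      cohorts[[cs]] <- cohort_table(
        as.data.frame(tab)[tab$cause == cs, , drop = FALSE],
        design = config$design)
  } else {
    for (i in seq_along(config$causes)) {
      cs <- config$causes[i]
      say("simulate: ", cs, " cohort (", config$design, " design)")
      beta0 <- default_cause_beta0(cs)
      args <- c(list(design = config$design,
                     ethnicities = config$ethnicities, cause = cs,
                     seed = config$seed + 1000L * i),
                config$generator)
      if (!is.null(beta0) && is.null(config$generator$beta0))
        args$beta0 <- beta0
      cohorts[[cs]] <- generate_cohort(do.call(generator_config, args))
    }
  }

  has_raw <- !anyNA(cohorts[[1L]]$eligible_deaths)
  for (cs in names(cohorts)) {
    write_cohort(cohorts[[cs]], file.path(outdir,
                                          paste0("cohort_", slug(cs), ".csv")))
    if (has_raw) {
      # Disclosure control applies to raw integer counts only, never to
      # model output.
      conf <- as.data.frame(cohorts[[cs]])
      conf$eligible_deaths_rr3 <- format_confidential(
        suppress_small(rr3(conf$eligible_deaths,
                           seed = config$seed + 7L)))
      utils::write.csv(
        conf[, c("ethnicity", "cause", "sex", "age_group", "group",
                 "person_years", "eligible_deaths_rr3")],
        file.path(outdir, paste0("counts_confidential_", slug(cs), ".csv")),
        row.names = FALSE)
    }
  }

  # --- stage: linkage weights ---------------------------------------
  weighted <- lapply(cohorts, function(tab) {
    if (anyNA(tab$eligible_deaths) || anyNA(tab$linked_deaths)) tab
    else apply_linkage_weights(tab, pooling = "broad_age")
  })
  say("linkage: weighted deaths total ",
      sprintf("%.1f", sum(weighted[[1L]]$deaths)), " (", names(weighted)[1L],
      ")")

  # Shared standard: combined exposure of the first cause's table.
  std_w <- standard_weights_from(weighted[[1L]])

  # --- stage: fit + standardise -------------------------------------
  all_summaries <- list()
  fits_by_cause <- list()
  manifest_conv <- list()
  for (ci in seq_along(weighted)) {
    cs <- names(weighted)[ci]
    say("fit: ", cs, " (", length(unique(weighted[[cs]]$ethnicity)),
        " ethnicity blocks)")
    m <- mcmc_base
    m$seed <- mcmc_base$seed + 100L * ci
    fits <- fit_hb_blocks(weighted[[cs]], mcmc = m)
    fits_by_cause[[cs]] <- fits
    for (nm in names(fits)) {
      f <- fits[[nm]]
      manifest_conv[[paste0(nm)]] <- list(max_split_rhat = max(f$rhat),
                                          min_ess = min(f$ess),
                                          dropped_strata =
                                            cell_key(f$dropped))
      export_draws(f, file.path(outdir, paste0("draws_", slug(nm), ".csv")),
                   per = config$per)
    }
    say("standardise: ", cs)
    all_summaries[[cs]] <- summarise_standardised(fits, std_w,
                                                  per = config$per)
  }
  summaries <- do.call(rbind, all_summaries)
  rownames(summaries) <- NULL
  write_summary(summaries, file.path(outdir, "summaries.csv"))

  # --- stage: report -------------------------------------------------
  table_out <- render_rate_table(summaries, layout = config$design)
  utils::write.csv(table_out, file.path(outdir, "rate_table.csv"),
                   row.names = FALSE)
  manifest <- list(
    package = "hbmort",
    version = as.character(utils::packageVersion("hbmort")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed, design = config$design, causes = names(cohorts),
    ethnicities = config$ethnicities, per = config$per,
    mcmc = unclass(mcmc_base), convergence = manifest_conv)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: outputs in ", outdir)
  invisible(list(summaries = summaries, table = table_out,
                 fits = fits_by_cause, manifest = manifest))
}

slug <- function(x) gsub("[^A-Za-z0-9]+", "_", x)

#' Format a rate or ratio cell
#'
#' @param median,lo,hi Summary values.
#' @param digits Decimal places (1 for rates, 2 for ratios).
#' @return `"m (lo,hi)"` at the requested precision.
#' @export
format_rate_cell <- function(median, lo, hi, digits = 1) {
  sprintf("%.*f (%.*f,%.*f)", digits, median, digits, lo, digits, hi)
}

#' Parse a formatted rate cell
#'
#' Inverse of [format_rate_cell()] at its printed precision; the reference
#' cell `"1"` parses to `c(1, NA, NA)`.
#'
#' @param cell Character cell like `"189.2 (167.8,213.2)"`.
#' @return Numeric vector `median`, `lo`, `hi`.
#' @export
parse_rate_cell <- function(cell) {
  if (identical(cell, "1")) return(c(median = 1, lo = NA, hi = NA))
  m <- regmatches(cell,
                  regexec("^([-0-9.]+) \\(([-0-9.]+),([-0-9.]+)\\)$", cell))[[1L]]
  if (length(m) != 4L) stop("unparseable cell: ", cell, call. = FALSE)
  c(median = as.numeric(m[2L]), lo = as.numeric(m[3L]),
    hi = as.numeric(m[4L]))
}

#' Render a publication-style rate table
#'
#' Lays out standardised rates and rate ratios as in a mortality report:
#' one row per ethnicity within each cause block; rate cells to one
#' decimal place, ratio cells to two; the reference ethnicity's
#' cross-ethnicity ratio cells rendered as `"1"`.
#'
#' @param summaries Data frame from [summarise_standardised()] (may span
#'   causes).
#' @param layout `"nativity"` (rates by nativity, ratios vs reference
#'   ethnicity, overseas- vs native-born ratio) or `"dor"` (rates by
#'   duration of residence, ratios vs reference ethnicity, each duration
#'   group vs the longest resident).
#' @return Data frame of formatted cells.
#' @export
render_rate_table <- function(summaries, layout) {
  layout <- match.arg(layout, names(DESIGN_GROUPS))
  groups <- design_groups(layout)
  ref_grp <- design_ref_group(layout)
  causes <- unique(summaries$cause)
  eths <- unique(summaries$ethnicity)
  ref_eth <- eths[!eths %in%
                    summaries$ethnicity[summaries$comparison ==
                                          "vs_ref_ethnicity"]][1L]

  cell_of <- function(cs, eth, grp, comparison, digits) {
    row <- summaries[summaries$cause == cs & summaries$ethnicity == eth &
                       summaries$group == grp &
                       summaries$comparison == comparison, , drop = FALSE]
    if (!nrow(row))
      stop("missing summary for ", paste(cs, eth, grp, comparison,
                                         sep = " / "), call. = FALSE)
    format_rate_cell(row$median, row$lo95, row$hi95, digits)
  }

  rows <- list()
  for (cs in causes) for (eth in eths) {
    r <- list(cause = cs, ethnicity = eth)
    for (g in groups)
      r[[paste0("rate_", g)]] <- cell_of(cs, eth, g, "rate", 1)
    for (g in groups)
      r[[paste0("rr_eth_", g)]] <- if (eth == ref_eth) "1" else
        cell_of(cs, eth, g, "vs_ref_ethnicity", 2)
    for (g in setdiff(groups, ref_grp))
      r[[paste0("rr_", g, "_vs_", ref_grp)]] <-
        cell_of(cs, eth, g, "vs_ref_group", 2)
    rows[[length(rows) + 1L]] <- as.data.frame(r, check.names = FALSE,
                                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
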