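# JAGS model strings.  Weighted death counts are non-integer, so the
# Poisson log-likelihood  -mu + y*log(mu)  is supplied explicitly through
# a Poisson-zeros likelihood node (per-stratum offset C keeps the rate
# positive).  The linear predictor uses the orthonormalised design matrix;
# stratum rates are invariant to that reparameterisation.
JAGS_HIER <- "
model {
  for (s in 1:S) {
    zeros[s] ~ dpois(phi[s])
    phi[s] <- mu[s] - y[s] * log(mu[s]) + C[s]
    log(lambda[s]) <- inprod(X[s, ], theta) + sigma * z[s]
    mu[s] <- py[s] * lambda[s]
    z[s] ~ dnorm(0, 1)
  }
  for (j in 1:P) { theta[j] ~ dnorm(0, coef_prec) }
  sigma ~ dnorm(0, sigma_prec) T(0, )
}"

JAGS_FIXED <- "
model {
  for (s in 1:S) {
    zeros[s] ~ dpois(phi[s])
    phi[s] <- mu[s] - y[s] * log(mu[s]) + C[s]
    log(lambda[s]) <- inprod(X[s, ], theta)
    mu[s] <- py[s] * lambda[s]
  }
  for (j in 1:P) { theta[j] ~ dnorm(0, coef_prec) }
}"

#' Specification of the hierarchical Poisson log-rate model
#'
#' Deaths in stratum \eqn{s} are modelled as
#' \eqn{d_s \sim \mathrm{Poisson}(T_s \lambda_s)} with
#' \eqn{\log \lambda_s = x_s^\top \beta + \epsilon_s},
#' \eqn{\epsilon_s \sim N(0, \sigma^2)}, where \eqn{x_s} holds an
#' intercept, sex, the linear age spline, and group (nativity or duration
#' of residence) terms.  The stratum effects \eqn{\epsilon_s} pool
#' information across strata, shrinking sparse-stratum rates toward the
#' covariate structure.  Priors are weakly informative: coefficients
#' \eqn{N(0, \mathrm{sd}=}`coef_prior_sd`\eqn{)} (applied on the
#' orthonormalised design scale) and \eqn{\sigma \sim}
#' Half-Normal(`sigma_prior_scale`).
#'
#' @param intercept_only Drop sex, age and group terms (used for
#'   single-stratum validation fits).
#' @param stratum_effect Include the Normal stratum effect; set `FALSE`
#'   for a pure fixed-effect (no-shrinkage) fit.
#' @param coef_prior_sd Prior standard deviation of the regression
#'   coefficients.
#' @param sigma_prior_scale Scale of the Half-Normal prior on the
#'   stratum-effect standard deviation.
#' @return A `model_spec` list.
#' @export
model_spec <- function(intercept_only = FALSE, stratum_effect = TRUE,
                       coef_prior_sd = 10, sigma_prior_scale = 1) {
  stopifnot(coef_prior_sd > 0, sigma_prior_scale > 0)
  structure(list(intercept_only = intercept_only,
                 stratum_effect = stratum_effect,
                 coef_prior_sd = coef_prior_sd,
                 sigma_prior_scale = sigma_prior_scale),
            class = "model_spec")
}

#' MCMC settings
#'
#' @param chains Number of chains (>= 2 so split-Rhat is meaningful).
#' @param adapt,warmup Adaptation and burn-in iterations per chain.
#' @param kept Kept draws per chain after thinning; `chains * kept` is at
#'   least 1000 at the defaults.
#' @param thin Thinning interval.
#' @param seed Integer seed; chain RNGs are derived from it, making fits
#'   reproducible draw-for-draw.
#' @return An `mcmc_config` list.
#' @export
mcmc_config <- function(chains = 2L, adapt = 1000L, warmup = 1000L,
                        kept = 2500L, thin = 1L, seed = 1L) {
  stopifnot(chains >= 2L, adapt >= 0L, warmup >= 0L, kept >= 1L, thin >= 1L)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), kept = as.integer(kept),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_config")
}

# Natural-scale design matrix of a stratum data frame.
build_design <- function(strata, design, spec) {
  if (spec$intercept_only)
    return(matrix(1, nrow(strata), 1, dimnames = list(NULL, "intercept")))
  basis <- spline_basis(scale_age(strata$age_group))
  X <- cbind(intercept = 1, sexF = as.numeric(strata$sex == "F"), basis)
  groups <- design_groups(design)
  ref <- design_ref_group(design)
  for (g in setdiff(groups, ref))
    X <- cbind(X, as.numeric(strata$group == g))
  colnames(X) <- c("intercept", "sexF", "age", "hinge1", "hinge2",
                   paste0("group", setdiff(groups, ref)))
  X
}

#' Fit the hierarchical Bayesian Poisson rate model to one cohort block
#'
#' Fits one ethnicity-by-cause block (each block is a separate model; use
#' [fit_hb_blocks()] to fit every block of a table).  Zero-exposure strata
#' cannot inform a rate and are dropped with a warning.  The sampler is
#' JAGS; the design matrix is QR-orthonormalised internally for mixing and
#' natural-scale coefficients are recovered by back-substitution.  A
#' convergence warning is raised unless split-Rhat < 1.05 and effective
#' sample size > 400 for every stratum rate.
#'
#' @param table A [cohort_table()] (or plain data frame with the cohort
#'   columns) containing a single ethnicity and cause.
#' @param spec A [model_spec()].
#' @param mcmc An [mcmc_config()].
#' @param design Stratification design; taken from the table's attribute
#'   when present.  Ignored for intercept-only specs.
#' @param quiet Suppress JAGS progress output.
#' @return An `hb_fit` with elements `rates` (draws x strata matrix of
#'   posterior rates per person-year, columns keyed by stratum), `strata`,
#'   `beta` (natural-scale coefficient draws), `sigma`, `rhat`, `ess`,
#'   and `dropped`.
#' @export
fit_hb <- function(table, spec = model_spec(), mcmc = mcmc_config(),
                   design = attr(table, "design"), quiet = TRUE) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_config"))
  strata <- as.data.frame(table)
  if (length(unique(strata$ethnicity)) > 1L ||
      length(unique(strata$cause)) > 1L)
    stop("fit_hb() fits one ethnicity x cause block; ",
         "use fit_hb_blocks() for a full table", call. = FALSE)
  if (is.null(design) && !spec$intercept_only)
    stop("design required when the table carries no design attribute",
         call. = FALSE)

  dropped <- strata[strata$person_years <= 0, , drop = FALSE]
  if (nrow(dropped)) {
    warning("dropping ", nrow(dropped), " zero-exposure stratum/strata: ",
            paste(cell_key(dropped), collapse = "; "), call. = FALSE)
    strata <- strata[strata$person_years > 0, , drop = FALSE]
  }
  if (!nrow(strata)) stop("no strata with positive exposure", call. = FALSE)
  if (any(!is.finite(strata$deaths)) || any(strata$deaths < 0))
    stop("non-finite or negative deaths; likelihood undefined",
         call. = FALSE)

  X <- build_design(strata, design, spec)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    stop("rank-deficient design: collinear column(s) ",
         paste(colnames(X)[setdiff(seq_len(ncol(X)), keep)],
               collapse = ", "), call. = FALSE)
  }
  S <- nrow(X)
  Q <- qr.Q(qrX) * sqrt(S)          # orthonormal columns, unit RMS
  Rs <- qr.R(qrX) / sqrt(S)         # X == Q %*% Rs

  y <- strata$deaths
  C <- ifelse(y > 0, y * log(y) - y, 0) + 10
  dat <- list(S = S, P = ncol(Q), X = Q, py = strata$person_years,
              y = y, zeros = rep(0, S), C = C,
              coef_prec = 1 / spec$coef_prior_sd^2)
  model_str <- if (spec$stratum_effect) JAGS_HIER else JAGS_FIXED
  if (spec$stratum_effect) dat$sigma_prec <- 1 / spec$sigma_prior_scale^2

  inits <- lapply(seq_len(mcmc$chains), function(i) {
    ini <- list(theta = rep(0, ncol(Q)),
                .RNG.name = "base::Mersenne-Twister",
                .RNG.seed = mcmc$seed + i)
    if (spec$stratum_effect) {
      ini$z <- rep(0, S)
      ini$sigma <- spec$sigma_prior_scale / 2
    }
    ini
  })

  run <- function() {
    jm <- rjags::jags.model(textConnection(model_str), data = dat,
                            inits = inits, n.chains = mcmc$chains,
                            n.adapt = mcmc$adapt, quiet = TRUE)
    if (mcmc$warmup > 0)
      stats::update(jm, mcmc$warmup, progress.bar = "none")
    monitor <- c("lambda", "theta", if (spec$stratum_effect) "sigma")
    rjags::coda.samples(jm, monitor, n.iter = mcmc$kept * mcmc$thin,
                        thin = mcmc$thin, progress.bar = "none")
  }
  sm <- if (quiet) suppressMessages(run()) else run()

  vn <- coda::varnames(sm)
  lam_names <- if ("lambda" %in% vn) "lambda" else
    sprintf("lambda[%d]", seq_len(S))
  chains <- lapply(sm, function(ch) as.matrix(ch))
  rates <- do.call(rbind, lapply(chains, function(m)
    m[, lam_names, drop = FALSE]))
  colnames(rates) <- cell_key(strata)

  theta_names <- if ("theta" %in% vn) "theta" else
    sprintf("theta[%d]", seq_len(ncol(Q)))
  theta <- do.call(rbind, lapply(chains, function(m)
    m[, theta_names, drop = FALSE]))
  beta <- t(backsolve(Rs, t(theta)))
  colnames(beta) <- colnames(X)
  sigma <- if (spec$stratum_effect)
    unlist(lapply(chains, function(m) m[, "sigma"])) else NULL

  lam_arr <- sapply(chains, function(m) m[, lam_names, drop = FALSE],
                    simplify = "array")   # kept x S x chains
  rhat <- apply(lam_arr, 2, function(m) split_rhat(m))
  ess <- as.numeric(coda::effectiveSize(sm[, lam_names, drop = FALSE]))
  names(rhat) <- names(ess) <- colnames(rates)

  if (max(rhat) >= 1.05 || min(ess) <= 400)
    warning(sprintf(paste0("convergence not reached: max split-Rhat %.3f, ",
                           "min ESS %.0f (contract: Rhat < 1.05, ESS > 400); ",
                           "increase kept draws or warmup"),
                    max(rhat), min(ess)), call. = FALSE)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("non-finite or nonpositive posterior rates", call. = FALSE)

  structure(list(rates = rates, strata = strata, beta = beta, sigma = sigma,
                 rhat = rhat, ess = ess, mcmc = mcmc, spec = spec,
                 design = design, dropped = dropped),
            class = "hb_fit")
}

#' Fit every ethnicity x cause block of a cohort table
#'
#' @inheritParams fit_hb
#' @param seed_offsets Each block gets `mcmc$seed + offset` with offsets
#'   0, 1, 2, ... in block order, so blocks are independently seeded but
#'   jointly reproducible.
#' @return Named list of `hb_fit` objects, keyed `"ethnicity|cause"`.
#' @export
fit_hb_blocks <- function(table, spec = model_spec(), mcmc = mcmc_config(),
                          quiet = TRUE, seed_offsets = TRUE) {
  stopifnot(inherits(table, "cohort_table"))
  design <- attr(table, "design")
  blocks <- unique(data.frame(ethnicity = table$ethnicity,
                              cause = table$cause,
                              stringsAsFactors = FALSE))
  fits <- vector("list", nrow(blocks))
  names(fits) <- paste(blocks$ethnicity, blocks$cause, sep = "|")
  for (i in seq_len(nrow(blocks))) {
    sub <- table[table$ethnicity == blocks$ethnicity[i] &
                   table$cause == blocks$cause[i], , drop = FALSE]
    m <- mcmc
    if (isTRUE(seed_offsets)) m$seed <- mcmc$seed + i - 1L
    fits[[i]] <- fit_hb(sub, spec = spec, mcmc = m, design = design,
                        quiet = quiet)
  }
  fits
}

# Split-Rhat of one parameter from a kept x chains draw matrix: each chain
# is halved, and the classic potential-scale-reduction statistic computed
# over the 2 * chains half-sequences.
split_rhat <- function(draws) {
  n <- nrow(draws) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j)
    cbind(draws[seq_len(n), j], draws[n + seq_len(n), j])))
  W <- mean(apply(halves, 2, stats::var))
  if (W == 0) return(1)
  B <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Scale posterior rate draws
#'
#' @param fit An `hb_fit`.
#' @param per Rate scale; the default reports deaths per 100,000
#'   person-years.
#' @return The draws x strata matrix of rates multiplied by `per`.
#' @export
posterior_rates <- function(fit, per = 1e5) {
  stopifnot(inherits(fit, "hb_fit"))
  if (!is.numeric(per) || length(per) != 1L || per <= 0)
    stop("per must be a positive scalar", call. = FALSE)
  fit$rates * per
}

#' Export posterior rate draws to CSV
#'
#' One row per draw, one column per stratum (header = stratum keys), for
#' external audit.
#'
#' @inheritParams posterior_rates
#' @param path Output path.
#' @export
export_draws <- function(fit, path, per = 1) {
  draws <- as.data.frame(posterior_rates(fit, per))
  utils::write.csv(draws, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.hb_fit <- function(x, ...) {
  cat("<hb_fit>", ncol(x$rates), "strata |", nrow(x$rates), "draws (",
      x$mcmc$chains, "chains ) | max split-Rhat",
      sprintf("%.3f", max(x$rhat)), "| min ESS",
      sprintf("%.0f", min(x$ess)), "\n")
  invisible(x)
}
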