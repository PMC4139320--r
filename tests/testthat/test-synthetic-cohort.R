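test_that("generation is deterministic and honours complete linkage", {
  cfg <- generator_config(design = "dor", seed = 5)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(nrow(a), 3L * 60L)

  full <- generate_cohort(generator_config(link_prob = 1, seed = 6))
  expect_identical(full$linked_deaths, full$eligible_deaths)
})

test_that("eligible deaths have the configured Poisson mean", {
  # noise off, exposure fixed, complete linkage: analytic mean per stratum
  cfg <- generator_config(design = "nativity", ethnicities = "Chinese",
                          sigma_strata = 0, py_cv = 0, link_prob = 1,
                          seed = 1)
  grid <- hbmort:::structural_log_rates(cfg)
  reps <- 500L
  sums <- 0
  for (s in seq_len(reps)) {
    cfg$seed <- s
    sums <- sums + generate_cohort(cfg)$eligible_deaths
  }
  # exposure is deterministic at py_cv = 0, and generate_cohort() emits
  # strata in the same grid order as the structural predictor
  cfg$seed <- 1L
  tab1 <- generate_cohort(cfg)
  expect_identical(paste(tab1$sex, tab1$age_group, tab1$group),
                   paste(grid$sex, grid$age_group, grid$group))
  mu <- tab1$person_years * exp(grid$eta)
  se <- sqrt(mu / reps)
  # family-wise bound over 40 strata: 4 SE per stratum keeps the overall
  # false-alarm probability below 40 * P(|Z| > 4) ~ 0.3%
  expect_true(all(abs(sums / reps - mu) <= 4 * se))
  # aggregate total is the sensitive check for any systematic bias
  expect_lt(abs(sum(sums) / reps - sum(mu)), 3 * sqrt(sum(mu) / reps))
})

test_that("true standardised rates are the structural dot product", {
  cfg <- generator_config(design = "nativity", seed = 2)
  tab <- generate_cohort(cfg)
  w <- standard_weights_from(tab)
  truth <- truth_standardised_rates(cfg, w, per = 1)

  # independent brute-force recomputation, cell by cell
  for (i in sample(nrow(truth), 3)) {
    acc <- 0
    for (sex in c("M", "F")) for (ag in age_groups()) {
      eta <- cfg$beta0[[truth$ethnicity[i]]] +
        cfg$beta_sex * (sex == "F") +
        sum(drop(spline_basis(scale_age(ag))) * cfg$beta_age) +
        cfg$group_effects[[truth$group[i]]]
      acc <- acc + w[[paste(sex, ag, sep = "|")]] * exp(eta)
    }
    expect_equal(truth$rate[i], acc)
  }

  # multiplicative group effect -> exact true rate ratio
  rr <- truth$rate[truth$group == "OSB"] / truth$rate[truth$group == "NZB"]
  expect_equal(rr, rep(0.67, 3))

  # no group effects -> shared standardised rate across groups
  cfg0 <- generator_config(design = "dor",
                           group_effects = c("0-9" = 0, "10-24" = 0,
                                             "25+" = 0), seed = 3)
  t0 <- truth_standardised_rates(cfg0, w)
  spread <- tapply(t0$rate, t0$ethnicity, function(r) diff(range(r)))
  expect_true(all(spread < 1e-12))
})

test_that("linkage-weighted deaths are unbiased for eligible deaths", {
  cfg <- generator_config(design = "nativity", ethnicities = "Chinese",
                          link_prob = 2 / 3, seed = 1)
  rel <- numeric(1000L)
  for (s in seq_along(rel)) {
    cfg$seed <- s
    tab <- generate_cohort(cfg)
    w <- apply_linkage_weights(tab, pooling = "broad_age")
    rel[s] <- (sum(w$deaths) - sum(tab$eligible_deaths)) /
      sum(tab$eligible_deaths)
  }
  expect_lt(abs(mean(rel)), 0.01)
})

test_that("generator configs round-trip through YAML and JSON", {
  cfg <- generator_config(design = "dor", sigma_strata = 0.2, seed = 77)
  for (ext in c(".yml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_generator_config(cfg, path)
    back <- read_generator_config(path)
    expect_equal(back, cfg)
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(link_prob = 0), "link_prob")
  expect_error(generator_config(sigma_strata = -1), "sigma_strata")
  expect_error(generator_config(beta0 = 1), "rates reach 1")
})
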