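test_that("standard weights are exposure shares summing to one", {
  tab <- tiny_cohort(seed = 31)
  w <- standard_weights_from(tab)
  expect_equal(sum(w), 1)
  expect_identical(length(w), 20L)

  # uniform exposure -> equal weights
  grid <- expand.grid(sex = c("M", "F"), age_group = age_groups(),
                      stringsAsFactors = FALSE)
  grid$person_years <- 1000
  wu <- standard_weights_from(grid)
  expect_equal(unname(wu), rep(1 / 20, 20))

  # hand-normalisation oracle on an exposure pattern shaped like a
  # published person-time table (heavy young/OSB cells)
  df <- data.frame(sex = rep(c("M", "F"), each = 3),
                   age_group = rep(c("25-29", "45-49", "70-74"), 2),
                   person_years = c(106797, 96357, 41070,
                                    141588, 117384, 43566))
  wh <- standard_weights_from(df)
  expect_equal(unname(wh[paste(df$sex, df$age_group, sep = "|")]),
               df$person_years / sum(df$person_years))
  expect_error(standard_weights_from(df[0, ]), "empty")
})

test_that("draw-wise direct standardisation is a weighted sum", {
  w2 <- c("M|45-49" = 0.5, "F|45-49" = 0.5)
  expect_equal(direct_standardise(named_draws(c(100, 300), names(w2)), w2),
               200)
  # equal rates in a draw pass through because weights sum to 1
  cells <- paste(rep(c("M", "F"), each = 10), age_groups(), sep = "|")
  w <- stats::setNames(rep(1 / 20, 20), cells)
  const <- named_draws(rep(7.5, 3 * 20), cells)
  expect_equal(direct_standardise(const, w), rep(7.5, 3))

  # brute-force dot-product oracle at machine precision
  set.seed(99)
  draws <- named_draws(stats::rgamma(5 * 20, 2, 1), cells)
  got <- direct_standardise(draws, w)
  oracle <- vapply(seq_len(nrow(draws)), function(d)
    sum(vapply(cells, function(cl) w[[cl]] * draws[d, cl], numeric(1))),
    numeric(1))
  expect_equal(got, oracle, tolerance = 1e-15)

  # linearity
  expect_equal(direct_standardise(3 * draws, w), 3 * got)

  expect_error(direct_standardise(draws[, -1], w), "M\\|25-29")
})

test_that("rate ratios are computed per draw", {
  x <- c(1.2, 0.8, 1.5)
  expect_equal(rate_ratio_draws(x, x), rep(1, 3))
  expect_equal(rate_ratio_draws(c(2, 4), c(1, 2)), c(2, 2))
  expect_error(rate_ratio_draws(1:3, 1:2), "differ")
  expect_error(rate_ratio_draws(1:3, c(1, 0, 2)), "nonpositive")
  # independent pairing permutes but preserves the draw set
  set.seed(1)
  den <- stats::runif(100, 1, 2)
  rr <- rate_ratio_draws(rep(1, 100), den, pairing = "independent",
                         seed = 3)
  expect_equal(sort(1 / rr), sort(den))
})

test_that("summaries are medians with interpolated 95% intervals", {
  expect_equal(summarise_draws(rep(3.2, 10)),
               c(median = 3.2, lo95 = 3.2, hi95 = 3.2))
  # sort-and-index oracle for type-7 interpolated percentiles on 1..1000
  x <- sample(1:1000)
  s <- summarise_draws(x)
  q7 <- function(p, n = 1000) { h <- (n - 1) * p + 1
    floor(h) + (h - floor(h)) * 1 }  # sorted values are 1..n so x_(i) = i
  expect_equal(unname(s), c(q7(0.5), q7(0.025), q7(0.975)))
  expect_equal(summarise_draws(x), summarise_draws(rev(sort(x))))
  expect_error(summarise_draws(numeric(0)), "at least 2")
  expect_error(summarise_draws(5), "at least 2")
})

test_that("the 10% tail rule classifies significance", {
  all_above <- rep(1.3, 50)
  s <- significance(all_above)
  expect_equal(s$pr_gt_1, 1)
  expect_true(s$significant)

  five_pct <- c(rep(1.2, 5), rep(0.9, 95))
  expect_true(significance(five_pct)$significant)
  expect_equal(significance(five_pct)$pr_gt_1, 0.05)

  half <- c(rep(1.2, 50), rep(0.9, 50))
  expect_false(significance(half)$significant)

  # draws exactly at 1 count as not-greater, and the flag is stable under
  # sub-1e-12 jitter
  ties <- c(rep(1, 95), rep(1.5, 5))
  s1 <- significance(ties)
  expect_equal(s1$pr_gt_1, 0.05)
  expect_true(s1$significant)
  s2 <- significance(ties + stats::runif(100, 0, 1e-13))
  expect_identical(s2$significant, s1$significant)
})

test_that("standardised summaries cover every group and comparison", {
  tab <- apply_linkage_weights(
    generate_cohort(generator_config(design = "nativity",
                                     ethnicities = c("Chinese", "Indian"),
                                     seed = 37)), pooling = "broad_age")
  w <- standard_weights_from(tab)
  fits <- expect_quiet_fit(fit_hb_blocks(tab, mcmc = fast_mcmc(seed = 12)))
  summ <- summarise_standardised(fits, w)
  expect_setequal(unique(summ$comparison),
                  c("rate", "vs_ref_group", "vs_ref_ethnicity"))
  expect_identical(sum(summ$comparison == "rate"), 4L)        # 2 eth x 2 grp
  expect_identical(sum(summ$comparison == "vs_ref_group"), 2L)
  expect_identical(sum(summ$comparison == "vs_ref_ethnicity"), 2L)
  expect_true(all(summ$lo95 <= summ$median & summ$median <= summ$hi95))
  ratios <- summ[summ$comparison != "rate", ]
  expect_true(all(ratios$pr_gt_1 >= 0 & ratios$pr_gt_1 <= 1))
  # the reference group's self-ratio is the constant 1
  std <- standardised_rate_draws(fits[[1]], w)
  self_rr <- rate_ratio_draws(std[, "NZB"], std[, "NZB"])
  expect_equal(self_rr, rep(1, nrow(std)))
})
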