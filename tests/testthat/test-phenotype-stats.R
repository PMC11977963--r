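records <- function(time, fate, group = "g") {
  data.frame(animal_id = sprintf("%s_%02d", group, seq_along(time)),
             group = group, time = time, fate = fate,
             stringsAsFactors = FALSE)
}

test_that("censoring taxonomy splits events from exclusions and logs them", {
  raw <- records(c(5, 10, 11, 12, 13), c("censored_crawl_off", rep("death", 4)))
  out <- apply_censoring(raw)
  expect_equal(out$analysis$status, c(0L, 1L, 1L, 1L, 1L))
  expect_equal(out$exclusion_log$n, 1L)
  expect_equal(out$exclusion_log$fate, "censored_crawl_off")
  all_death <- apply_censoring(records(1:4, rep("death", 4)))
  expect_equal(nrow(all_death$exclusion_log), 0L)
  expect_error(apply_censoring(records(1, "vanished")), class = "unknown_fate")
})

test_that("Kaplan-Meier equals the empirical survival without censoring", {
  km <- km_estimate(records(c(1, 2, 3, 4), rep("death", 4)))
  expect_equal(km_survival_at(km, 2.5), 0.5)
  expect_equal(km_survival_at(km, c(0.5, 1, 4)), c(1, 0.75, 0))
  set.seed(8)
  t <- ceiling(rexp(60, 1 / 15))
  km2 <- km_estimate(records(t, rep("death", 60)))
  grid <- 0:40
  emp <- vapply(grid, function(g) mean(t > g), numeric(1))
  expect_equal(km_survival_at(km2, grid), emp, tolerance = 1e-12)
})

test_that("Kaplan-Meier with censoring matches the hand product-limit oracle", {
  raw <- records(c(3, 5, 5, 7, 8, 8),
                 c("death", "censored_bagging", "death", "death",
                   "censored_crawl_off", "death"))
  an <- apply_censoring(raw)$analysis
  km <- km_estimate(raw)
  at <- c(2, 3, 5, 6, 7, 8, 10)
  expect_equal(km_survival_at(km, at), km_oracle(an$time, an$status, at),
               tolerance = 1e-12)
  expect_warning(km0 <- km_estimate(records(c(2, 3),
                                            rep("censored_bagging", 2))),
                 "degenerate")
  expect_true(all(km0$survival == 1))
})

test_that("log-rank is null on identical groups and label-symmetric", {
  a <- records(c(10, 12, 14, 16, 18), rep("death", 5), "a")
  b <- records(c(10, 12, 14, 16, 18), rep("death", 5), "b")
  same <- logrank_test(a, b)
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)
  set.seed(9)
  c1 <- records(ceiling(rexp(40, 1 / 18)), rep("death", 40), "c1")
  c2 <- records(ceiling(rexp(40, 1 / 24)), rep("death", 40), "c2")
  fwd <- logrank_test(c1, c2)
  rev <- logrank_test(c2, c1)
  expect_equal(fwd$chi2, rev$chi2, tolerance = 1e-12)
  expect_equal(fwd$p, rev$p, tolerance = 1e-12)
  # invariant under monotone time rescaling
  c1s <- c1; c1s$time <- sqrt(c1s$time)
  c2s <- c2; c2s$time <- sqrt(c2s$time)
  expect_equal(logrank_test(c1s, c2s)$chi2, fwd$chi2, tolerance = 1e-12)
  all_cens <- records(c(5, 6), rep("censored_bagging", 2), "z")
  expect_error(logrank_test(a, all_cens), class = "no_events")
})

test_that("lifespan comparison reports events-only means and extension", {
  ctrl <- records(c(18, 20, 22), rep("death", 3), "ctrl")
  trt <- records(c(24, 26, 28), rep("death", 3), "trt")
  cmp <- lifespan_comparison(ctrl, trt)
  expect_equal(cmp$control_mean, 20)
  expect_equal(cmp$treated_mean, 26)
  expect_equal(cmp$percent_extension, 30)
  same <- lifespan_comparison(ctrl, ctrl)
  expect_equal(same$percent_extension, 0)
  # censored animals do not enter the events-only mean
  trt_c <- rbind(trt, records(25, "censored_crawl_off", "trt"))
  expect_equal(lifespan_comparison(ctrl, trt_c)$treated_mean, 26)
  # restricted-mean policy integrates the KM curve instead; by hand:
  # S = 1 on [0,24), 3/4 on [24,26), 3/8 on [26,28) with the censor at 25
  rmean <- lifespan_comparison(ctrl, trt_c, mean_policy = "restricted")
  expect_equal(rmean$treated_mean, 24 + 2 * 3 / 4 + 2 * 3 / 8)
})

test_that("chi-square matches closed forms and a multinomial null", {
  flat <- chi_square_morphology(rbind(c(10, 10, 10), c(10, 10, 10)))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  skew <- chi_square_morphology(rbind(c(30, 10), c(10, 30)))
  expect_equal(skew$chi2, 20)   # four cells, each (10^2)/20
  expect_equal(skew$dof, 1)
  # Monte-Carlo multinomial null: tail of the Pearson statistic under
  # independence with the observed margins
  obs <- rbind(c(12, 18, 10), c(20, 11, 9))
  got <- chi_square_morphology(obs)
  set.seed(12)
  colp <- colSums(obs) / sum(obs)
  stat1 <- function() {
    sim <- rbind(t(rmultinom(1, sum(obs[1, ]), colp)),
                 t(rmultinom(1, sum(obs[2, ]), colp)))
    if (any(colSums(sim) == 0)) return(NA_real_)
    suppressWarnings(unname(chisq.test(sim, correct = FALSE)$statistic))
  }
  sims <- replicate(20000, stat1())
  mc_p <- mean(sims >= got$chi2 - 1e-9, na.rm = TRUE)
  expect_lt(abs(mc_p - got$p), 0.02)
  expect_error(chi_square_morphology(rbind(c(0, 0), c(1, 2))),
               class = "zero_marginal")
})

test_that("relative intestinal width is the dimensionless shrinkage ratio", {
  expect_equal(relative_intestinal_width(20, 4, 40), 0.4)
  expect_equal(relative_intestinal_width(7, 7, 30), 0)
  expect_equal(relative_intestinal_width(20 * 3, 4 * 3, 40 * 3), 0.4)
  expect_error(relative_intestinal_width(5, 7, 30), class = "bad_width")
  expect_error(relative_intestinal_width(5, 2, 0), class = "bad_width")
})

test_that("inhibition ratio interpolates linearly between control and blank", {
  expect_equal(inhibition_ratio(0.9, 0.9, 0.1), 0)
  expect_equal(inhibition_ratio(0.1, 0.9, 0.1), 100)
  expect_equal(inhibition_ratio(0.5, 0.9, 0.1), 50)
  expect_error(inhibition_ratio(0.5, 0.1, 0.2), class = "bad_absorbance")
})

test_that("fixed-endpoint stress assays compare surviving proportions", {
  res <- endpoint_survival_test(18, 20, 9, 20)
  expect_equal(res$prop_a, 0.9)
  expect_equal(res$prop_b, 0.45)
  expect_lt(res$p, 0.01)
  same <- endpoint_survival_test(10, 20, 10, 20)
  expect_equal(same$p, 1, tolerance = 1e-12)
})
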