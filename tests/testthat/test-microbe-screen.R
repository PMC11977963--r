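test_that("OD600 and CFU conversions are the stated linear formulas", {
  expect_equal(od600_to_cells(0), 0)
  expect_equal(od600_to_cells(0.1), 8e4)
  expect_equal(od600_to_cells(1.0), 8e5)
  expect_equal(od600_to_cells(0.5, cells_per_od = 1e6), 5e5)
  expect_error(od600_to_cells(-0.1), class = "bad_od")
  expect_equal(cfu_per_ml(0, 1e4, 10), 0)
  expect_equal(cfu_per_ml(37, 1e4, 10), 3.7e7)
  expect_equal(cfu_per_ml(37, 1e4, 20), 3.7e7 / 2)
  # linear in the count argument
  expect_equal(cfu_per_ml(74, 1e4, 10), 2 * cfu_per_ml(37, 1e4, 10))
  expect_error(cfu_per_ml(5, 1e4, 0), class = "bad_volume")
})

test_that("growth summaries match quadrature and react to inhibition", {
  curve <- gen_growth_curve(1.2, rate = 0.6, lag = 2, n_hours = 30,
                            noise_sd = 0)
  s <- growth_curve_summary(curve)
  # fine-grid quadrature oracle on the same logistic trajectory
  fine <- gen_growth_curve(1.2, rate = 0.6, lag = 2, n_hours = 30,
                           noise_sd = 0)
  tt <- seq(0, 30, by = 0.01)
  te <- pmax(tt - 2, 0)
  od <- 1.2 * 0.05 * exp(0.6 * te) / (1.2 + 0.05 * (exp(0.6 * te) - 1))
  auc_fine <- sum(diff(tt) * (head(od, -1) + tail(od, -1)) / 2)
  expect_lt(abs(s$auc - auc_fine) / auc_fine, 0.01)
  slow <- growth_curve_summary(gen_growth_curve(1.2, rate = 0.3, lag = 2,
                                                n_hours = 30, noise_sd = 0))
  expect_lt(slow$auc, s$auc)
  expect_gt(slow$time_to_half_max, s$time_to_half_max)
  flat <- growth_curve_summary(data.frame(time = 0:5, od600 = rep(0.7, 6)))
  expect_equal(flat$max_od, 0.7)
  expect_equal(flat$auc, 0.7 * 5)
  expect_equal(flat$time_to_half_max, 0)
  expect_warning(zero <- growth_curve_summary(data.frame(time = 0:5,
                                                         od600 = rep(0, 6))),
                 "undefined")
  expect_true(is.na(zero$time_to_half_max))
})

ext_cells <- function() {
  data.frame(
    strain = c("OP50", "BW25113", "dupp_dudp"),
    dose = 400,
    percent_extension = c(30, 34.7, 7.5),
    logrank_p = c(1e-5, 1e-5, 0.1376),
    n = 80
  )
}

test_that("extension matrix normalizes to the reference and is scale-free", {
  m <- extension_matrix(ext_cells(), "OP50", 400)
  expect_equal(m$normalized_extension[m$strain == "OP50"], 1)
  expect_equal(m$normalized_extension[m$strain == "dupp_dudp"], 7.5 / 30)
  scaled <- ext_cells()
  scaled$percent_extension <- scaled$percent_extension * 3
  m2 <- extension_matrix(scaled, "OP50", 400)
  expect_equal(m2$normalized_extension, m$normalized_extension)
  expect_error(extension_matrix(ext_cells(), "HT115", 400),
               class = "missing_reference")
  zero_ref <- ext_cells(); zero_ref$percent_extension[1] <- 0
  expect_warning(mz <- extension_matrix(zero_ref, "OP50", 400), "withheld")
  expect_true(all(is.na(mz$normalized_extension)))
  expect_equal(mz$percent_extension[mz$strain == "BW25113"], 34.7)
})

test_that("dependence calls reproduce the knockout/rescue taxonomy", {
  wt_double <- list(percent_extension = 34.7, logrank_p = 1e-5)
  double_ko <- list(percent_extension = 7.5, logrank_p = 0.1376)
  expect_equal(as.character(classify_dependence(wt_double, double_ko)$call),
               "required")
  wt_single <- list(percent_extension = 31.3, logrank_p = 1e-5)
  single_ko <- list(percent_extension = 24.5, logrank_p = 1e-5)
  rescue <- list(percent_extension = 39.2, logrank_p = 1e-5)
  partial <- classify_dependence(wt_single, single_ko, rescue)
  expect_equal(as.character(partial$call), "partially_required")
  expect_true(isTRUE(partial$rescue_supported))
  same <- classify_dependence(wt_single, wt_single)
  expect_equal(as.character(same$call), "not_required")
  expect_equal(same$rescue_supported, "not_tested")
  weak_wt <- list(percent_extension = 10, logrank_p = 0.2)
  expect_error(classify_dependence(weak_wt, single_ko),
               class = "wildtype_not_significant")
})

test_that("dependence calls are monotone in the mutant extension", {
  wt <- list(percent_extension = 30, logrank_p = 1e-5)
  rank <- c(required = 1, partially_required = 2, not_required = 3)
  prev <- 3
  for (ext in seq(30, -5, by = -2.5)) {
    call <- classify_dependence(wt, list(percent_extension = ext,
                                         logrank_p = 1e-5))$call
    expect_lte(rank[[as.character(call)]], prev)
    prev <- rank[[as.character(call)]]
  }
})

test_that("simulated strain cohorts recover the planted dependence structure", {
  # planted per-strain drug effects: WT full, single KO half, double KO none
  effects <- c(WT = 0.30, single_ko = 0.15, double_ko = 0.0)
  cells <- do.call(rbind, lapply(names(effects), function(s) {
    tr <- survival_truth(20, effects[[s]], censor_rate = 0.1, n_per_arm = 150,
                         hazard_family = "weibull")
    sv <- gen_survival(tr, seed = match(s, names(effects)) * 101L)
    cmp <- lifespan_comparison(sv[sv$group == "control", ],
                               sv[sv$group == "treated", ])
    data.frame(strain = s, dose = 400,
               percent_extension = cmp$percent_extension,
               logrank_p = cmp$logrank_p, n = 150)
  }))
  m <- extension_matrix(cells, "WT", 400)
  ord <- m$percent_extension[match(names(effects), m$strain)]
  expect_true(all(diff(ord) < 0))   # planted ordering WT > single > double
  wt_row <- cells[cells$strain == "WT", ]
  expect_equal(as.character(classify_dependence(
    wt_row, cells[cells$strain == "double_ko", ])$call), "required")
  expect_equal(as.character(classify_dependence(
    wt_row, cells[cells$strain == "single_ko", ])$call), "partially_required")
})
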