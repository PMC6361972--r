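# 4PL fitting, absolute IC50, fold-selectivity, GR metrics and PDL.

dose_series <- 1e4 / 10^(0:9)   # 10-point 10-fold dilution, 1e-5..1e4 nM

test_that("noise-free 4PL recovery across the parameter grid", {
  grid <- expand.grid(bottom = c(0, 0.2), top = c(0.8, 1),
                      hill = c(0.5, 1, 2), ec50 = c(1, 10, 100))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    v <- g$bottom + (g$top - g$bottom) / (1 + (dose_series / g$ec50)^g$hill)
    f <- fit_4pl(dose_series, v)
    expect_true(f$converged)
    expect_lt(abs(f$bottom - g$bottom), 1e-6)
    expect_lt(abs(f$top - g$top), 1e-6)
    expect_lt(abs(f$hill - g$hill) / g$hill, 1e-6)
    expect_lt(abs(f$ec50_rel_nM - g$ec50) / g$ec50, 1e-6)
  }
})

test_that("noisy fits recover EC50 within tolerance", {
  tr <- data.frame(compound_id = "A", cell_line = "L", bottom = 0, top = 1,
                   hill = 1, ec50_nM = 10)
  d <- gen_dose_response(dr_sim_config(tr, top_dose_nM = 10 * 3^4,
                                       dilution_factor = 3, n_points = 8L,
                                       replicates = 3L, noise_sd = 0.05,
                                       seed = 4L))$data
  f <- fit_4pl(d$concentration_nM, d$viability)
  expect_true(f$converged)
  expect_lt(abs(f$ec50_rel_nM - 10) / 10, 0.2)
})

test_that("degenerate and invalid inputs are flagged or rejected", {
  expect_error(fit_4pl(c(1, 10, 100), c(1, 0.5, 0)), ">= 4 distinct")
  flat <- fit_4pl(dose_series, rep(0.8, length(dose_series)))
  expect_true(flat$degenerate)
  expect_false(flat$converged)
  expect_error(fit_4pl(dose_series, c(NA, rnorm(9))), "finite")
  # monotone-increasing input: converges, flagged non-inhibitory
  inc <- fit_4pl(dose_series, 1 - 1 / (1 + (dose_series / 10)^1))
  expect_true(inc$converged)
  expect_true(inc$non_inhibitory)
})

test_that("absolute IC50 closed form and censoring", {
  mk_fit <- function(bottom, top, hill, ec50) {
    v <- bottom + (top - bottom) / (1 + (dose_series / ec50)^hill)
    fit_4pl(dose_series, v)
  }
  # midpoint identity: (top + bottom)/2 = 0.5 => absolute == relative
  f <- mk_fit(0, 1, 1, 10)
  expect_equal(absolute_ic50(f)$ic50_nM, f$ec50_rel_nM, tolerance = 1e-6)
  # closed form 10 * (0.3 / 0.5)
  f <- mk_fit(0, 0.8, 1, 10)
  expect_equal(absolute_ic50(f)$ic50_nM, 6, tolerance = 1e-5)
  # and conversely, midpoint != 0.5 => absolute != relative
  expect_gt(abs(absolute_ic50(f)$ic50_nM - f$ec50_rel_nM), 1)
  # bottom >= 0.5: curve never reaches 0.5
  f <- mk_fit(0.6, 1, 1, 10)
  ic <- absolute_ic50(f)
  expect_true(is.na(ic$ic50_nM))
  expect_equal(ic$censored, "above_range")
  expect_match(ic$label, "^>")
  # top <= 0.5: below 0.5 everywhere
  f <- mk_fit(0, 0.45, 1, 10)
  expect_equal(absolute_ic50(f)$censored, "below_range")
})

test_that("fold selectivity reproduces the published integers and is scale invariant", {
  expect_equal(fold_selectivity(194, 7)$reported_fold, 28)
  expect_equal(fold_selectivity(186, 9)$reported_fold, 21)
  expect_equal(fold_selectivity(1564, 276)$reported_fold, 6)
  expect_equal(fold_selectivity(194, 7)$fold, 194 / 7)
  expect_equal(fold_selectivity(5, 5)$fold, 1)
  for (k in c(0.1, 3, 1000)) {
    expect_equal(fold_selectivity(k * 194, k * 7)$fold,
                 fold_selectivity(194, 7)$fold, tolerance = 1e-12)
  }
  # censored input yields a bound, not a number
  cens <- list(ic50_nM = NA_real_, censored = "above_range",
               label = ">10000")
  fs <- fold_selectivity(cens, 100)
  expect_true(fs$bound)
  expect_match(fs$label, "^>")
  expect_error(fold_selectivity(-1, 5), "positive")
})

test_that("GR closed forms, bounds and monotonicity", {
  g <- compute_gr(c(1, 10, 100), c(100, 200, 800), x0 = 100, x_ctrl = 800,
                  fit_gr50 = FALSE)$gr_table$gr
  expect_equal(g[1], 0)                    # x_c = x0: cytostatic
  expect_equal(g[3], 1)                    # x_c = x_ctrl: no effect
  expect_equal(g[2], 2^(1 / 3) - 1, tolerance = 1e-12)  # 1 of 3 doublings
  # strictly increasing in x_c
  xc <- seq(50, 1000, by = 50)
  gr <- compute_gr(seq_along(xc), xc, 100, 800, fit_gr50 = FALSE)$gr_table$gr
  expect_true(all(diff(gr) > 0))
  expect_true(all(gr > -1))
  expect_error(compute_gr(1, 100, 100, 90), "no control growth")
  expect_error(compute_gr(1, 0, 100, 800), "> 0")
})

test_that("GR50 is the 0.5 crossing of the fitted GR curve", {
  # construct counts whose GR curve is exactly 4PL(bottom 0, top 1, ec50 20)
  conc <- 1e3 / 2^(0:9)
  x0 <- 100; x_ctrl <- 800
  gr_true <- 1 / (1 + (conc / 20)^1)
  x_c <- x0 * (x_ctrl / x0)^log2(gr_true + 1)   # invert the GR formula
  res <- compute_gr(conc, x_c, x0, x_ctrl)
  expect_equal(res$gr50$ic50_nM, 20, tolerance = 1e-4)
})

test_that("IC50/GR50 correlation behaves on constructed panels", {
  expect_equal(correlate_ic50_gr50(c(1, 5, 20, 80), c(1, 5, 20, 80))$rho, 1)
  expect_equal(correlate_ic50_gr50(c(1, 5, 20, 80), c(80, 20, 5, 1))$rho, -1)
  set.seed(8)
  ic <- 10^runif(15, 0, 3)
  gr <- ic * 10^rnorm(15, 0, 0.1)   # monotone plus small noise
  out <- correlate_ic50_gr50(ic, gr)
  expect_gt(out$rho, 0.9)
  expect_lt(out$p_value, 0.01)
  # censored pairs are excluded and counted
  ic[1] <- NA
  expect_equal(correlate_ic50_gr50(ic, gr)$n_censored, 1L)
  expect_error(correlate_ic50_gr50(c(1, NA), c(1, 2)), ">= 3")
})

test_that("PDL formula, constants and additivity", {
  expect_equal(pdl(50000, 100000)$pdl, 3.32 * log10(2))   # ~0.9994
  expect_equal(pdl(1000, 1000, pdl_prev = 5)$pdl, 5)
  expect_equal(pdl(50000, 400000)$pdl, 3.32 * log10(8))   # 2.998
  expect_equal(pdl(50000, 100000, exact_log2 = TRUE)$pdl, 1)
  expect_error(pdl(0, 10), "> 0")
  # additive over consecutive passages (exactly, for either constant)
  two_step <- pdl(200, 800, pdl_prev = pdl(100, 200)$pdl)$pdl
  expect_equal(two_step, pdl(100, 800)$pdl, tolerance = 1e-12)
})

test_that("fit_dr_table fits grouped series and labels censored IC50s", {
  tr <- data.frame(compound_id = rep("cmpA", 2),
                   cell_line = c("lineR", "lineS"),
                   bottom = 0, top = 1, hill = 1, ec50_nM = c(500, 25))
  d <- gen_dose_response(dr_sim_config(tr, top_dose_nM = 1e4,
                                       dilution_factor = 3, n_points = 9L,
                                       replicates = 3L, noise_sd = 0.02,
                                       seed = 6L))$data
  tab <- fit_dr_table(d)
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$converged))
  expect_equal(tab$ic50_abs_nM[tab$cell_line == "lineR"], 500,
               tolerance = 0.2)
  expect_equal(tab$ic50_abs_nM[tab$cell_line == "lineS"], 25,
               tolerance = 0.2)
})
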