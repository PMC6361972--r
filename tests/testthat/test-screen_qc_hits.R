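# Normalization, QC statistics and the three-criterion hit classifier.

test_that("normalize_plate divides well totals by the vehicle mean", {
  lay <- tiny_layout(n_cpd = 1L, n_veh = 3L, n_pos = 2L)
  rec <- records_from_totals(list(
    A01 = c(1000, 1000), B01 = c(1000, 1000), C01 = c(1000, 1000),
    A12 = c(1000, 100), B12 = c(1000, 100),
    A02 = c(550, 900)))
  nm <- normalize_plate(rec, lay)
  cpd <- nm[nm$kind == "compound", ]
  expect_equal(cpd$green_norm, 0.55)
  expect_equal(cpd$red_norm, 0.9)
  # vehicle wells average exactly 1 per channel
  expect_equal(mean(nm$green_norm[nm$kind == "vehicle"]), 1)
  expect_equal(mean(nm$red_norm[nm$kind == "vehicle"]), 1)
})

test_that("normalization identity and unequal-vehicle cases", {
  lay <- tiny_layout(n_cpd = 1L, n_veh = 2L, n_pos = 2L)
  rec <- records_from_totals(list(
    A01 = c(700, 700), B01 = c(700, 700), A12 = c(700, 700),
    B12 = c(700, 700), A02 = c(700, 700)))
  nm <- normalize_plate(rec, lay)
  expect_true(all(abs(nm$green_norm - 1) < 1e-12))
  expect_true(all(abs(nm$red_norm - 1) < 1e-12))

  rec2 <- records_from_totals(list(
    A01 = c(900, 900), B01 = c(1100, 1100), A12 = c(900, 900),
    B12 = c(900, 900), A02 = c(500, 500)))
  nm2 <- normalize_plate(rec2, lay)
  expect_equal(nm2$green_norm[nm2$kind == "compound"], 0.5)

  rec3 <- records_from_totals(list(
    A01 = c(0, 100), B01 = c(0, 100), A12 = c(1, 1), B12 = c(1, 1),
    A02 = c(1, 1)))
  expect_error(normalize_plate(rec3, lay), "vehicle mean is zero.*green")
})

test_that("qc_stats matches the closed forms and degenerate limits", {
  s <- qc_stats(1.0, 0.1, 0.1, 0.05)
  expect_equal(s$z_prime, 0.5)
  expect_equal(s$s_over_n, 9)
  expect_equal(s$s_over_b, 10)

  expect_equal(qc_stats(1, 0, 0.1, 0)$z_prime, 1)
  expect_true(is.na(qc_stats(1, 0.1, 1, 0.1)$z_prime))   # mu_n == mu_p
  expect_true(is.na(qc_stats(1, 0.1, 0, 0.05)$s_over_b)) # mu_p == 0
  expect_lte(qc_stats(0.9, 0.3, 0.2, 0.3)$z_prime, 1)
})

test_that("compute_qc uses sample SD, needs >= 2 controls per side, warns on green", {
  nm <- data.frame(plate_id = "P1",
                   kind = c(rep("vehicle", 3), rep("positive_control", 3)),
                   red_norm = c(0.9, 1.0, 1.1, 0.05, 0.10, 0.15),
                   green_norm = 1)
  qc <- compute_qc(nm)
  expect_equal(qc$mu_n, 1); expect_equal(qc$sd_n, 0.1)   # sd with n-1
  expect_equal(qc$z_prime, 0.5)
  expect_equal(qc$s_over_n, 9)
  expect_equal(qc$s_over_b, 10)
  expect_warning(compute_qc(nm, channel = "green"), "positive control")
  expect_error(compute_qc(nm[-(1:2), ]), ">= 2")
})

test_that("compute_qc emits per-plate rows plus a screen average", {
  nm <- rbind(
    data.frame(plate_id = "P1", kind = rep(c("vehicle", "positive_control"),
                                           each = 2),
               red_norm = c(0.95, 1.05, 0.1, 0.2), green_norm = 1),
    data.frame(plate_id = "P2", kind = rep(c("vehicle", "positive_control"),
                                           each = 2),
               red_norm = c(0.9, 1.1, 0.1, 0.3), green_norm = 1))
  qc <- compute_qc(nm)
  expect_equal(qc$plate_id, c("P1", "P2", "screen-average"))
  expect_equal(qc$z_prime[3], mean(qc$z_prime[1:2]))
})

test_that("Z' decreases monotonically in either control SD", {
  sds <- seq(0, 0.2, by = 0.05)
  z_n <- vapply(sds, function(s) qc_stats(1, s, 0.1, 0.05)$z_prime, 1)
  z_p <- vapply(sds, function(s) qc_stats(1, 0.1, 0.1, s)$z_prime, 1)
  expect_true(all(diff(z_n) < 0))
  expect_true(all(diff(z_p) < 0))
})

test_that("classify_viability applies the published criteria", {
  cases <- data.frame(
    g = c(0.90, 0.55, 0.30, 0.30, 1.00, 0.00),
    r = c(0.20, 0.41, 0.95, 0.30, 1.00, 0.30),
    want = c("emt_selective", "inactive", "epithelial_selective",
             "pan_cytotoxic", "inactive", "pan_cytotoxic"))
  got <- classify_viability(cases$g, cases$r)
  expect_equal(got$class, cases$want)
  # the boundary case fails only criterion (c)
  expect_true(got$emt_a[2] && got$emt_b[2] && !got$emt_c[2])
  expect_equal(got$ratio_rg[1], 0.2 / 0.9)
  expect_true(is.na(got$ratio_rg[6]))   # green 0: ratio undefined
})

test_that("hit classes are mutually exclusive and exhaustive", {
  set.seed(13)
  g <- runif(500, 0, 1.3); r <- runif(500, 0, 1.3)
  cls <- classify_viability(g, r)$class
  expect_true(all(cls %in% c("emt_selective", "epithelial_selective",
                             "pan_cytotoxic", "inactive")))
  both <- classify_viability(g, r)
  expect_false(any((both$emt_a & both$emt_b & both$emt_c) &
                     (both$epi_a & both$epi_b & both$epi_c)))
})

test_that("classification is invariant to well order and plate-wide rescaling", {
  lay <- tiny_layout(n_cpd = 3L, n_veh = 2L, n_pos = 2L)
  rec <- records_from_totals(list(
    A01 = c(1000, 1000), B01 = c(1000, 1000), A12 = c(1000, 160),
    B12 = c(1000, 170), A02 = c(900, 200), B02 = c(300, 950),
    C02 = c(1000, 990)))
  base <- call_hits(normalize_plate(rec, lay))

  shuf <- rec[sample.int(nrow(rec)), ]
  expect_equal(call_hits(normalize_plate(shuf, lay)), base)

  rec4 <- rec; rec4$count <- rec4$count * 4L   # detector gain cancels
  expect_equal(call_hits(normalize_plate(rec4, lay)), base)
  expect_equal(base$class[match(c("C01", "C02", "C03"), base$compound_id)],
               c("emt_selective", "epithelial_selective", "inactive"))
})

test_that("excluded compounds keep their class but leave the hit lists", {
  lay <- tiny_layout(n_cpd = 2L, n_veh = 2L, n_pos = 2L)
  rec <- records_from_totals(list(
    A01 = c(1000, 1000), B01 = c(1000, 1000), A12 = c(1000, 160),
    B12 = c(1000, 170), A02 = c(900, 200), B02 = c(880, 210)))
  calls <- call_hits(normalize_plate(rec, lay),
                     exclusions = c(C02 = "auto-fluorescent"))
  expect_equal(calls$class, c("emt_selective", "emt_selective"))
  expect_true(calls$excluded[calls$compound_id == "C02"])
  expect_equal(hit_lists(calls)$emt_selective, "C01")
})

test_that("planted hits are recovered exactly on well-separated screens", {
  eff <- default_screen_effects(n_inactive = 400L)
  sim <- gen_screen_plates(screen_sim_config(eff, baseline = 800,
                                             noise = "poisson", seed = 31L))
  nm <- normalize_screen(sim$records, sim$layouts)
  hl <- hit_lists(call_hits(nm))
  truth_emt <- sort(sim$truth$compound_id[sim$truth$true_class == "emt_selective"])
  truth_epi <- sort(sim$truth$compound_id[sim$truth$true_class == "epithelial_selective"])
  expect_equal(sort(hl$emt_selective), truth_emt)
  expect_equal(sort(hl$epithelial_selective), truth_epi)
})
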