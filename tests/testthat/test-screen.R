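test_that("efficacy ratios divide cancer by marrow percent and flag zero denominators", {
  expect_equal(efficacy_ratio(50, 100), 0.5)
  expect_equal(efficacy_ratio(0, 70), 0)
  # 19.8% remaining cancer colonies over 38% marrow -> 0.52 at 2 decimals
  expect_equal(round(efficacy_ratio(19.8, 38), 2), 0.52)
  expect_warning(r <- efficacy_ratio(10, 0), "undefined")
  expect_true(is.na(r))
  # scale invariance
  x <- c(10, 55, 80); y <- c(90, 100, 40)
  for (k in c(0.1, 3, 117)) {
    expect_equal(efficacy_ratio(k * x, k * y), efficacy_ratio(x, y))
  }
})

test_that("colony tables load with row-level validation and replicate flags", {
  tab <- make_colony_table(colony_sim_spec(seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  loaded <- load_colony_table(path)
  expect_equal(nrow(loaded), nrow(tab))
  expect_true(all(attr(loaded, "duplicates") == FALSE))

  # corrupt two rows: negative percent, bad timepoint
  bad <- tab
  bad$percent_of_control[4] <- -5
  bad$timepoint_days[9] <- 11
  utils::write.csv(bad, path, row.names = FALSE)
  loaded <- load_colony_table(path)
  expect_equal(nrow(loaded), nrow(tab) - 2)
  errs <- attr(loaded, "errors")
  expect_setequal(errs$row, c(4, 9))
  expect_match(errs$reason[errs$row == 4], "negative")

  # duplicated wells are retained but flagged
  dup <- rbind(tab[1:3, ], tab[1, ])
  utils::write.csv(dup, path, row.names = FALSE)
  loaded <- load_colony_table(path)
  expect_equal(nrow(loaded), 4)
  expect_equal(sum(attr(loaded, "duplicates")), 2)
  expect_error(load_colony_table(withr::local_tempfile(fileext = ".csv")),
               "cannot read")
})

test_that("bundled marrow table carries 38 compounds at both timepoints", {
  tb <- bundled_tables()
  expect_equal(nrow(tb$table1), 38)
  expect_true(all(is.finite(tb$table1$day8)))
  expect_true(all(is.finite(tb$table1$day14)))
  expect_equal(tb$table1$day8[tb$table1$compound == "Dxr2-017"], 70)
  # untested entries print "-" and parse to NA; HT116 spelling is verbatim
  expect_true(any(is.na(tb$table2$ratio)))
  expect_true("HT116" %in% tb$table2$cell_line)
  expect_equal(tb$table2$ratio[tb$table2$compound_id == "Dxr2-017" &
                                 tb$table2$cell_line == "HT29"], 0)
  expect_equal(tb$table4$ratio[tb$table4$compound_id == "Dxr2-017" &
                                 tb$table4$cell_line == "LNCaP"], 0.49)
})

test_that("relative activity excludes untested lines and rounds half up", {
  ratios <- data.frame(
    compound_id = "X", site = "S", cell_line = sprintf("L%d", 1:8),
    concentration = 40,
    ratio = c(0.1, 0.2, 0.3, 0.4, 0.49, 0.7, 0.9, NA))
  expect_equal(relative_activity("X", ratios, 40), 71)  # 5/7, 0.49 active
  ratios$ratio <- c(rep(0.6, 7), NA)
  expect_equal(relative_activity("X", ratios, 40), 0)
  ratios$ratio[1:4] <- 0.2                              # 4/7 = 57.1
  expect_equal(relative_activity("X", ratios, 40), 57)
  expect_error(relative_activity("Y", ratios, 40), "no tested")
})

test_that("site summaries pool sub-threshold ratios with n-1 SEM", {
  ratios <- data.frame(
    compound_id = rep(c("A", "B"), each = 4),
    site = "S", cell_line = rep(sprintf("L%d", 1:4), 2),
    concentration = 40,
    ratio = c(0.1, 0.3, 0.8, 0.9, 0.7, 0.8, 0.9, 1.0))
  ss <- site_summary("S", ratios, 40, tested_compounds = c("A", "B", "C"))
  expect_equal(ss$n_tested, 3)
  expect_equal(ss$n_active, 1)
  expect_equal(ss$percent_active, 33)
  # one active compound: pooled stats equal its own sub-threshold stats
  expect_equal(ss$pooled_mean, mean(c(0.1, 0.3)))
  expect_equal(ss$pooled_sem, stats::sd(c(0.1, 0.3)) / sqrt(2))
  expect_equal(ss$relative_activity_range, c(50, 50))
  # single sub-threshold ratio: SEM degenerates to 0
  ratios$ratio <- c(0.4, 0.6, 0.8, 0.9, 0.7, 0.8, 0.9, 1.0)
  ss <- site_summary("S", ratios, 40)
  expect_equal(ss$pooled_sem, 0)
  expect_equal(ss$pooled_mean, 0.4)
  # no active compounds
  ratios$ratio <- ratios$ratio + 1
  ss <- site_summary("S", ratios, 40)
  expect_equal(ss$percent_active, 0)
  expect_true(is.na(ss$pooled_mean))
})

test_that("marrow flags derive from day 8 and recovery from day 14", {
  prof <- marrow_flags_and_recovery(
    day8 = c(79, 80, 70, 99, 65),
    day14 = c(112, 85, 57, 120, 64))
  expect_equal(prof$inhibition_flag_10, c(TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(prof$inhibition_flag_30, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(prof$recovery,
               c("recovered", "partial", "none", "not_applicable", "none"))
})

test_that("IC50 interpolation is exact at crossings and refuses extrapolation", {
  f <- ic50_estimate(c(1, 5, 25), c(90, 50, 10))
  expect_true(f$estimable)
  expect_equal(f$ic50, 5)
  f <- ic50_estimate(c(1, 10), c(80, 90))       # monotone increasing
  expect_false(f$estimable)
  expect_true(is.na(f$ic50))
  f <- ic50_estimate(c(1, 10), c(80, 70))       # never reaches 50
  expect_false(f$estimable)
  # dense zero-noise logistic curve: parameter recovery within 10%
  conc <- 10^seq(-3, 1, length.out = 40)
  pct <- 100 * (1 - conc^1.3 / (conc^1.3 + 0.02^1.3))
  f <- ic50_estimate(conc, pct)
  expect_true(f$estimable)
  expect_lt(abs(f$ic50 - 0.02) / 0.02, 0.1)
})

test_that("efficacy tables built from simulated colonies respect the Hill truth", {
  spec <- colony_sim_spec(seed = 42, noise_sd = 0)
  tab <- make_colony_table(spec)
  # inert compounds: percent of control stays at (1 - emax-tail) ~ 100
  eff <- efficacy_table_from_colonies(tab)
  sel <- spec$compounds$compound_id[spec$compounds$site == spec$selective_site][1]
  r <- eff$ratio[eff$compound_id == sel & eff$concentration == 40]
  expect_true(all(r < 0.5))
  expect_equal(sort(unique(eff$concentration)), sort(spec$concentrations))
})
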