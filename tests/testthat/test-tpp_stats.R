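# Build a well-behaved fits table directly: QC metrics default to passing
# values so individual rules can be exercised in isolation.
make_fits <- function(ids, treatment, replicate, tm,
                      cell_line = "lineA", layout = "lysate",
                      r2 = 0.95, plateau = 0.1, min_slope = -0.1) {
  data.frame(feature_id = ids, cell_line = cell_line, treatment = treatment,
             layout = layout, replicate = replicate, p = plateau,
             a = tm * 30, b = 30, tm = tm, r2 = r2, min_slope = min_slope,
             rss = 0.01, converged = TRUE, status = "ok",
             plateau = plateau, stringsAsFactors = FALSE)
}

drug_vs_vehicle <- comparison_spec(
  "drug/vehicle",
  list(cell_line = "lineA", treatment = "drug", layout = "lysate"),
  list(cell_line = "lineA", treatment = "vehicle", layout = "lysate"))

test_that("identical sides give zero shifts and zero hits", {
  set.seed(1)
  ids <- sprintf("P%02d", 1:30)
  tm <- runif(30, 45, 55)
  fits <- rbind(make_fits(ids, "vehicle", 1L, tm),
                make_fits(ids, "vehicle", 2L, tm),
                make_fits(ids, "drug", 1L, tm),
                make_fits(ids, "drug", 2L, tm))
  res <- compare_conditions(fits, drug_vs_vehicle)
  expect_true(all(res$dtm_1 == 0 & res$dtm_2 == 0))
  expect_equal(sum(res$significant), 0)
})

test_that("discordant-sign shifts are rejected with reason SIGN", {
  set.seed(2)
  ids <- sprintf("P%02d", 1:40)
  tm_v1 <- runif(40, 45, 55); tm_v2 <- tm_v1 + rnorm(40, 0, 0.05)
  tm_d1 <- tm_v1 + rnorm(40, 0, 0.05); tm_d2 <- tm_v2 + rnorm(40, 0, 0.05)
  tm_d1[1] <- tm_v1[1] + 4; tm_d2[1] <- tm_v2[1] - 4   # the decoy
  fits <- rbind(make_fits(ids, "vehicle", 1L, tm_v1),
                make_fits(ids, "vehicle", 2L, tm_v2),
                make_fits(ids, "drug", 1L, tm_d1),
                make_fits(ids, "drug", 2L, tm_d2))
  res <- compare_conditions(fits, drug_vs_vehicle)
  row <- res[res$feature_id == "P01", ]
  expect_false(row$significant)
  expect_false(row$same_sign)
  expect_match(row$reasons, "SIGN")
})

test_that("curve-quality gate produces exact reason codes", {
  good <- list(converged = TRUE, tm = 50, r2 = 0.95, plateau = 0.1,
               min_slope = -0.1)
  expect_true(qc_filter(good, good)$pass)

  fat <- good; fat$plateau <- 0.35
  out <- qc_filter(good, fat)   # vehicle-side plateau is gated
  expect_false(out$pass)
  expect_equal(out$reasons, "PLATEAU")

  poor <- good; poor$r2 <- 0.75
  expect_equal(qc_filter(poor, good)$reasons, "R2")

  shallow <- good; shallow$min_slope <- -0.02
  expect_equal(qc_filter(good, shallow)$reasons, "SLOPE")

  nomelt <- good; nomelt$tm <- NA_real_
  expect_equal(qc_filter(nomelt, good)$reasons, "NOMELT")
})

test_that("features on one side only are reported as unpaired, not dropped", {
  set.seed(3)
  ids <- sprintf("P%02d", 1:20)
  tm <- runif(20, 45, 55)
  fits <- rbind(make_fits(ids, "vehicle", 1L, tm),
                make_fits(ids, "vehicle", 2L, tm),
                make_fits(ids[-1], "drug", 1L, tm[-1]),
                make_fits(ids[-1], "drug", 2L, tm[-1]))
  res <- compare_conditions(fits, drug_vs_vehicle)
  expect_equal(res$status[res$feature_id == "P01"], "unpaired")
  expect_match(res$reasons[res$feature_id == "P01"], "UNPAIRED")
  expect_equal(nrow(res), 20)
})

test_that("hit verdicts are invariant to feature order and temperature offset", {
  cfg <- sim_config(seed = 31, n_features = 150)
  sim <- simulate_tpp_experiment(cfg)
  tab <- tpp_table(as.data.frame(
    sim$table[sim$table$cell_line == cfg$cell_lines[2], ]))
  fits <- fit_melting_table(tab)
  sp <- comparison_spec(
    "drug/vehicle",
    list(cell_line = cfg$cell_lines[2], treatment = "drug",
         layout = "lysate"),
    list(cell_line = cfg$cell_lines[2], treatment = "vehicle",
         layout = "lysate"))
  res <- compare_conditions(fits, sp)

  shuffled <- fits[sample(nrow(fits)), ]
  res2 <- compare_conditions(shuffled, sp)
  expect_equal(res2[order(res2$feature_id), "significant"],
               res[order(res$feature_id), "significant"])

  offset <- fits; offset$tm <- offset$tm + 2   # both sides relabeled
  res3 <- compare_conditions(offset, sp)
  expect_equal(res3$significant, res$significant)
})

test_that("raising the planted shift never lowers sensitivity", {
  sens <- vapply(c(1, 2.5, 4), function(mag) {
    cfg <- sim_config(seed = 17, n_features = 150, shift_fraction = 0.1,
                      shift_magnitude = mag)
    sim <- simulate_tpp_experiment(cfg)
    tab <- tpp_table(as.data.frame(
      sim$table[sim$table$cell_line == cfg$cell_lines[2], ]))
    fits <- fit_melting_table(tab)
    sp <- comparison_spec(
      "drug/vehicle",
      list(cell_line = cfg$cell_lines[2], treatment = "drug",
           layout = "lysate"),
      list(cell_line = cfg$cell_lines[2], treatment = "vehicle",
           layout = "lysate"))
    res <- compare_conditions(fits, sp)
    truth <- sim$truth$shifted_set
    length(intersect(res$feature_id[res$significant], truth)) / length(truth)
  }, 0)
  expect_true(all(diff(sens) >= 0))
  expect_gt(sens[3], 0.8)
})

test_that("hit-count summary reproduces the standard comparison layout", {
  expect_equal(nrow(count_significant(list(), list())), 0)

  specs <- standard_comparisons(c("SK-Mel-24", "SK-Mel-28"))
  labels <- vapply(specs, `[[`, "", "label")
  expect_length(specs, 8)
  expect_equal(labels[1:4], c(
    "SK-Mel-24 Hsp90i/DMSO", "SK-Mel-28 Hsp90i/DMSO",
    "SK-Mel-28 DMSO/SK-Mel-24 DMSO", "SK-Mel-28 Hsp90i/SK-Mel-24 Hsp90i"))
  expect_equal(vapply(specs, function(s) s$side_a$layout, ""),
               rep(c("lysate", "intact"), each = 4))

  # low-noise limit: planted shifter count is recovered exactly
  cfg <- sim_config(seed = 19, n_features = 240, shift_fraction = 0.05,
                    shift_magnitude = 5, noise_sd = 0.002,
                    line_shift_fraction = 0)
  sim <- simulate_tpp_experiment(cfg)
  tab <- tpp_table(as.data.frame(
    sim$table[sim$table$cell_line == cfg$cell_lines[2], ]))
  fits <- fit_melting_table(tab)
  sp <- comparison_spec(
    "SK-Mel-28 Hsp90i/DMSO",
    list(cell_line = cfg$cell_lines[2], treatment = "drug",
         layout = "lysate"),
    list(cell_line = cfg$cell_lines[2], treatment = "vehicle",
         layout = "lysate"))
  res <- compare_conditions(fits, sp)
  summ <- count_significant(list(res), list(sp))
  expect_equal(summ$n_significant, length(sim$truth$shifted_set))
  expect_equal(summ$comparison, "SK-Mel-28 Hsp90i/DMSO")
  expect_setequal(res$feature_id[res$significant], sim$truth$shifted_set)
})
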