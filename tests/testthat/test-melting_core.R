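test_that("profile normalization is exact, idempotent, and flags bad refs", {
  raw <- c(100, 90, 50, 10, 5, 4, 3, 2, 1, 1)
  n1 <- normalize_profile(raw)
  expect_true(n1$usable)
  expect_equal(n1$y, raw / 100)
  expect_identical(n1$y[1], 1)
  expect_equal(normalize_profile(n1$y)$y, n1$y)   # idempotent

  expect_false(normalize_profile(c(0, raw[-1]))$usable)
  expect_false(normalize_profile(c(NA, raw[-1]))$usable)
})

test_that("Tm closed form agrees with a numeric root finder", {
  # p = 0 reduces to Tm = a/b
  expect_equal(compute_tm(0, 550, 10), 55)
  # general case against bisection on f(T) - 0.5
  tm <- compute_tm(0.2, 500, 9)
  root <- uniroot(function(T) melt_sigmoid(T, 0.2, 500, 9) - 0.5,
                  c(20, 100), tol = 1e-10)$root
  expect_equal(tm, root, tolerance = 1e-8)
  # curve never crossing 0.5
  expect_true(is.na(compute_tm(0.6, 550, 10)))
  # extrapolation guard
  expect_true(is.na(compute_tm(0, 900, 10, t_range = c(37, 67), guard = 5)))
})

test_that("sigmoid fitting recovers noiseless truth and handles edge cases", {
  y <- melt_sigmoid(DEFAULT_TEMPS, 0, 550, 10)
  f <- fit_melting_curve(DEFAULT_TEMPS, y)
  expect_equal(f$tm, 55, tolerance = 1e-6)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  # the defining property of Tm holds on the fitted curve
  expect_equal(melt_sigmoid(f$tm, f$p, f$a, f$b), 0.5, tolerance = 1e-6)

  # noisy profile at a fixed seed stays close to the closed-form Tm
  set.seed(42)
  yn <- melt_sigmoid(DEFAULT_TEMPS, 0.1, 520, 9.8) * exp(rnorm(10, 0, 0.02))
  fn <- fit_melting_curve(DEFAULT_TEMPS, yn)
  expect_lt(abs(fn$tm - compute_tm(0.1, 520, 9.8)), 0.5)

  # flat profile: no decay signal, no fabricated parameters
  ff <- fit_melting_curve(DEFAULT_TEMPS, rep(1, 10))
  expect_false(ff$converged)
  expect_identical(ff$status, "flat")
  expect_true(is.na(ff$tm))

  # too few observed channels
  y2 <- y; y2[c(2, 5, 8)] <- NA
  expect_identical(fit_melting_curve(DEFAULT_TEMPS, y2)$status, "unusable")
})

test_that("fitted curves stay in range and r2 ignores feature labels", {
  set.seed(7)
  for (i in 1:20) {
    prof <- make_profile(DEFAULT_TEMPS, runif(1, 0, 0.25), runif(1, 44, 58),
                         runif(1, 26, 40))
    y <- prof$y * exp(rnorm(10, 0, 0.02))
    f <- fit_melting_curve(DEFAULT_TEMPS, y)
    vals <- melt_sigmoid(seq(37, 67, by = 0.5), f$p, f$a, f$b)
    expect_true(all(vals > 0 & vals <= 1 + f$p))
    expect_true(melt_sigmoid(f$tm, f$p, f$a, f$b) - 0.5 < 1e-6)
  }
})

test_that("peptide aggregation is the channel-wise median", {
  prof <- make_profile(DEFAULT_TEMPS, 0.1, 50, 30)$y
  expect_equal(aggregate_to_protein(rbind(prof)), prof,
               ignore_attr = TRUE)
  p2 <- make_profile(DEFAULT_TEMPS, 0.1, 54, 30)$y
  p3 <- make_profile(DEFAULT_TEMPS, 0.1, 46, 30)$y
  agg <- aggregate_to_protein(rbind(prof, p2, p3))
  expect_equal(agg, apply(rbind(prof, p2, p3), 2, median),
               ignore_attr = TRUE)

  # discordant peptides: aggregate-then-fit differs from per-peptide fits,
  # and both views are available for diagnosis
  far1 <- make_profile(DEFAULT_TEMPS, 0, 44, 30)$y
  far2 <- make_profile(DEFAULT_TEMPS, 0, 60, 30)$y
  rowsdf <- do.call(rbind, lapply(1:2, function(i) {
    df <- data.frame(feature_id = sprintf("PROTX_pep%d", i),
                     feature_level = "peptide", cell_line = "lineA",
                     treatment = "vehicle", layout = "lysate",
                     replicate = 1L, stringsAsFactors = FALSE)
    df[paste0("T", DEFAULT_TEMPS)] <-
      as.list((if (i == 1) far1 else far2) * 1e6)
    df
  }))
  tab <- tpp_table(rowsdf)
  pep_fits <- fit_melting_table(tab, level = "asis")
  prot_fits <- fit_melting_table(tab, level = "protein")
  expect_equal(nrow(pep_fits), 2)
  expect_equal(nrow(prot_fits), 1)
  expect_gt(abs(mean(pep_fits$tm) - prot_fits$tm), 0.01)
})

test_that("cross-experiment median normalization corrects planted distortion", {
  # four identical experiments -> exact identity factors
  cfg <- sim_config(seed = 13, n_features = 60, noise_sd = 0,
                    shift_fraction = 0, line_shift_fraction = 0)
  tab <- simulate_tpp_experiment(cfg)$table
  mn <- median_normalize(tab, min_features = 50)
  expect_true(mn$applied)
  expect_equal(mn$n_subset, 60)
  expect_true(all(abs(mn$factors - 1) < 1e-9))

  # scale one experiment by 1.1 at one temperature -> factor 1/1.1 recovered
  ic <- tpp_intensity_cols(tab)
  distorted <- as.data.frame(tab)
  sel <- distorted$cell_line == cfg$cell_lines[1] &
    distorted$treatment == "vehicle" & distorted$replicate == 1
  distorted[sel, ic[5]] <- distorted[sel, ic[5]] * 1.1
  mn2 <- median_normalize(tpp_table(distorted), min_features = 50)
  exp_key <- paste(cfg$cell_lines[1], "vehicle", "lysate", 1, sep = "|")
  expect_equal(mn2$factors[exp_key, 5], 1 / 1.1, tolerance = 1e-6)
  others <- setdiff(rownames(mn2$factors), exp_key)
  expect_true(all(abs(mn2$factors[others, ] - 1) < 1e-9))

  # below the joint-subset minimum: skipped with identity factors
  expect_warning(mn3 <- median_normalize(tab, min_features = 1000),
                 "skipped")
  expect_false(mn3$applied)
  expect_true(all(mn3$factors == 1))
})
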