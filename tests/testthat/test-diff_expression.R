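# Minimal expression table built in code: two groups x 3 replicates.
make_expr <- function(mat_a, mat_b, level = "protein", loc = NULL) {
  n <- nrow(mat_a)
  feats <- data.frame(
    feature_id = sprintf("P%03d", seq_len(n)),
    feature_level = level,
    localization_probability = if (is.null(loc)) rep(NA_real_, n) else loc,
    stringsAsFactors = FALSE)
  samples <- data.frame(
    cell_line = "lineR",
    treatment = rep(c("Hsp90i", "DMSO"), each = 3),
    replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  expression_table(feats, cbind(mat_a, mat_b), samples)
}
GA <- list(cell_line = "lineR", treatment = "Hsp90i")
GB <- list(cell_line = "lineR", treatment = "DMSO")

test_that("identical groups give t = 0, p = 1, fold change 1", {
  m <- matrix(2^rnorm(12, 20), nrow = 2)
  tab <- make_expr(m[, 1:3, drop = FALSE], m[, 1:3, drop = FALSE])
  d <- ttest_differential(tab, GA, GB)
  expect_equal(d$t_stat, c(0, 0))
  expect_equal(d$p_value, c(1, 1))
  expect_equal(d$fold_change, c(1, 1))
  expect_equal(d$regulated, c("none", "none"))
})

test_that("t statistics and p-values match the textbook formulas to 1e-10", {
  set.seed(5)
  n <- 50
  ma <- matrix(2^(rnorm(n * 3, 20, 1)), nrow = n)
  mb <- matrix(2^(rnorm(n * 3, 20, 1)), nrow = n)
  tab <- make_expr(ma, mb)
  d <- ttest_differential(tab, GA, GB)
  for (i in seq_len(n)) {
    o <- oracle_ttest(log2(ma[i, ]), log2(mb[i, ]))
    expect_equal(d$t_stat[i], o$t, tolerance = 1e-10)
    expect_equal(d$p_value[i], o$p, tolerance = 1e-10)
  }
})

test_that("regulation flags follow the exact threshold semantics", {
  # engineer group means to exact ratios; sd chosen so p ~ 0.04 or not
  build <- function(ratio, spread) {
    base <- c(19.9, 20, 20.1) * 1
    a <- 2^(base + log2(ratio)); b <- 2^base
    d <- ttest_differential(make_expr(rbind(a * spread), rbind(b)), GA, GB)
    d
  }
  up <- build(1.6, 1)
  expect_true(up$p_value < 0.05 && up$fold_change >= 1.5)
  expect_equal(up$regulated, "up")
  near <- build(1.4, 1)
  expect_equal(near$regulated, "none")    # significant p but |FC| < 1.5
  down <- ttest_differential(
    make_expr(rbind(2^c(19.9, 20, 20.1)), rbind(2^(c(19.9, 20, 20.1) + 1))),
    GA, GB)
  expect_equal(down$fold_change, -2, tolerance = 1e-9)
  expect_equal(down$regulated, "down")

  # sweeping thresholds re-derives the flags with no hidden state
  set.seed(6)
  ma <- matrix(2^(rnorm(90, 20, 1)), nrow = 30)
  mb <- matrix(2^(rnorm(90, 19.5, 1)), nrow = 30)
  tab <- make_expr(ma, mb)
  for (pm in c(0.01, 0.05, 0.2)) {
    for (fm in c(1.2, 1.5, 2)) {
      d <- ttest_differential(tab, GA, GB, p_max = pm, fc_min = fm)
      manual <- ifelse(d$p_value < pm & d$fold_change >= fm, "up",
                       ifelse(d$p_value < pm & d$fold_change <= -fm,
                              "down", "none"))
      expect_equal(d$regulated, manual)
    }
  }
})

test_that("features with under-replicated groups are untested with reason", {
  ma <- rbind(2^c(20, NA, NA), 2^c(20, 20.1, 19.9))
  mb <- rbind(2^c(19, 19.1, 18.9), 2^c(19, 19.1, 18.9))
  d <- ttest_differential(make_expr(ma, mb), GA, GB)
  expect_false(d$tested[1])
  expect_match(d$reason[1], "fewer than 2")
  expect_true(d$tested[2])
})

test_that("localization filter is inclusive at 0.75 and phospho-only", {
  m <- matrix(2^rnorm(18, 20), nrow = 3)
  tab <- make_expr(m[, 1:3], m[, 4:6], level = "phosphopeptide",
                   loc = c(0.74, 0.75, 0.9))
  kept <- suppressMessages(filter_phospho(tab))
  expect_equal(nrow(kept$features), 2)
  expect_equal(attr(kept, "n_removed"), 1)
  expect_setequal(kept$features$localization_probability, c(0.75, 0.9))

  all_in <- make_expr(m[, 1:3], m[, 4:6], level = "phosphopeptide",
                      loc = c(0.8, 0.9, 1))
  expect_equal(nrow(suppressMessages(filter_phospho(all_in))$features), 3)

  prot <- make_expr(m[, 1:3], m[, 4:6])
  expect_error(filter_phospho(prot), "phosphopeptide")
})

test_that("subtractive and intersection logic match brute-force enumeration", {
  a <- structure(c("A", "B", "C"), direction = "up",
                 class = "regulated_set")
  b <- structure("B", direction = "up", class = "regulated_set")
  expect_equal(as.character(subtractive_unique(a, b)), c("A", "C"))
  d <- structure("Z", direction = "up", class = "regulated_set")
  expect_equal(as.character(subtractive_unique(a, d)), c("A", "B", "C"))
  bd <- structure("B", direction = "down", class = "regulated_set")
  expect_error(subtractive_unique(a, bd), "direction mismatch")

  out <- intersect_settings(list(s1 = c("X", "Y", "Z"), s2 = c("X", "Z"),
                                 s3 = "X"))
  expect_equal(out$shared, "X")
  expect_equal(out$membership$s3, c(TRUE, FALSE, FALSE))
  expect_equal(intersect_settings(list(a = "A", b = "B"))$shared,
               character(0))

  set.seed(8)
  universe <- sprintf("F%02d", 1:30)
  for (i in 1:300) {
    s1 <- sample(universe, sample(0:20, 1))
    s2 <- sample(universe, sample(0:20, 1))
    s3 <- sample(universe, sample(0:20, 1))
    r1 <- structure(s1, direction = "up", class = "regulated_set")
    r2 <- structure(s2, direction = "up", class = "regulated_set")
    expect_equal(as.character(subtractive_unique(r1, r2)),
                 oracle_setdiff(s1, s2))
    expect_equal(intersect_settings(list(a = s1, b = s2, c = s3))$shared,
                 oracle_intersect_all(list(s1, s2, s3)))
    # idempotence and order-invariance
    expect_equal(intersect_settings(list(a = s1, b = s2))$shared,
                 intersect_settings(list(a = s2, b = s1))$shared)
  }
})

test_that("kinase annotation is plain set logic with recorded sources", {
  kinome <- gene_set_library(list(kinome = c("K1", "K2", "K3", "K9")))
  druggable <- gene_set_library(list(druggable = c("K2", "K8")))
  set9 <- c("K1", "K2", "K3", sprintf("N%d", 1:6))
  ann <- annotate_kinases(set9, kinome, druggable)
  expect_length(ann$kinases, 3)
  expect_equal(ann$druggable_kinases, "K2")

  empty <- annotate_kinases(character(0), kinome, druggable)
  expect_length(empty$kinases, 0)
  expect_error(annotate_kinases(set9, gene_set_library(list())), "empty")

  # hand enumeration on a <= 20-feature fixture with phosphosite ids
  sites <- c("K1_pS10", "K1_pT22", "K3_pY5", "N1_pS1")
  ann2 <- annotate_kinases(sites, kinome, druggable)
  expect_equal(ann2$kinases, c("K1", "K3"))
})
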