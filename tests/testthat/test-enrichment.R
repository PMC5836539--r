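test_that("hypergeometric upper tail behaves at the degenerate ends", {
  lib <- gene_set_library(list(T1 = c("A", "B", "C")))
  universe <- sprintf("G%02d", 1:20)
  names_fix <- c("A", "B", "C", sprintf("G%02d", 4:20))
  lib2 <- gene_set_library(list(T1 = c("A", "B", "C")))

  # zero overlap -> p = 1 exactly
  res <- overrepresentation(c("G04", "G05"), lib2, names_fix)
  expect_equal(res$p_value, 1)

  # query = universe -> every term fully overlaps, p = 1
  res2 <- overrepresentation(names_fix, lib2, names_fix)
  expect_equal(res2$overlap, 3)
  expect_equal(res2$p_value, 1)

  expect_error(overrepresentation("X", lib2, character(0)), "empty universe")
  expect_error(overrepresentation("ZZZ", lib2, names_fix),
               "outside the universe")
})

test_that("p is monotone in overlap and ties break deterministically", {
  universe <- sprintf("G%02d", 1:20)
  term <- universe[1:8]
  lib <- gene_set_library(list(T1 = term))
  p_by_overlap <- vapply(1:5, function(k) {
    query <- c(term[seq_len(k)], universe[9:(13 - k)])
    overrepresentation(query, lib, universe)$p_value
  }, 0)
  expect_true(all(diff(p_by_overlap) < 0))

  # equal p: ordering falls back to overlap then term id
  lib2 <- gene_set_library(list(B = universe[1:4], A = universe[1:4]))
  r <- overrepresentation(universe[1:4], lib2, universe)
  expect_equal(r$term, c("A", "B"))
})

test_that("BH adjustment equals the direct step-up procedure", {
  p <- c(0.001, 0.02, 0.03, 0.4, 0.9)
  m <- length(p)
  stepup <- rev(cummin(rev(p * m / seq_len(m))))
  expect_equal(p.adjust(p, "BH"), pmin(stepup, 1))
  universe <- sprintf("G%02d", 1:20)
  lib <- gene_set_library(list(T1 = universe[1:5], T2 = universe[3:9],
                               T3 = universe[10:12]))
  r <- overrepresentation(universe[1:6], lib, universe)
  ord <- order(r$p_value)
  manual <- rev(cummin(rev(r$p_value[ord] * 3 / seq_len(3))))
  expect_equal(r$p_adj[ord], pmin(manual, 1))
})

test_that("reporting filter applies strict p and overlap cutoffs", {
  res <- data.frame(term = c("a", "b", "c", "d"),
                    overlap = c(8, 7, 20, 8),
                    p_value = c(0.01, 0.01, 0.06, 0.049))
  kept <- kea_filter(res)
  expect_setequal(kept$term, c("a", "d"))   # overlap 7 and p 0.06 both drop
  expect_equal(nrow(kea_filter(res[0, ])), 0)
})

test_that("phosphosite sets collapse to one query entry per substrate", {
  q <- phosphosite_to_substrate_query(c("P1_pS10", "P1_pT20", "P2_pS5"))
  expect_equal(as.character(q), c("P1", "P2"))
  expect_length(phosphosite_to_substrate_query(character(0)), 0)
  expect_warning(q2 <- phosphosite_to_substrate_query(c("P1_pS10", "JUNK")),
                 "skipped")
  expect_equal(as.character(q2), "P1")
})

test_that("a planted active kinase ranks first by enrichment p", {
  cfg <- sim_config(seed = 23, n_features = 400,
                    feature_level = "phosphopeptide", de_effect = 8,
                    expr_noise_sd = 0.1,
                    reg_counts = c(shared = 30, resistant_only = 40,
                                   sensitive_only = 30))
  sim <- simulate_expression_study(cfg)
  tab <- suppressMessages(filter_phospho(sim$table))
  res_line <- cfg$cell_lines[2]; sens_line <- cfg$cell_lines[1]
  d_res <- ttest_differential(tab, list(cell_line = res_line,
                                        treatment = "Hsp90i"),
                              list(cell_line = res_line, treatment = "DMSO"))
  d_sen <- ttest_differential(tab, list(cell_line = sens_line,
                                        treatment = "Hsp90i"),
                              list(cell_line = sens_line, treatment = "DMSO"))
  uniq <- subtractive_unique(regulated_set(d_res, "up"),
                             regulated_set(d_sen, "up"))
  query <- suppressWarnings(phosphosite_to_substrate_query(uniq))
  universe <- unique(strip_feature_suffix(tab$features$feature_id))
  # wire 30 of the planted substrates into a kinase term, plus decoys
  planted <- head(intersect(unique(strip_feature_suffix(
    sim$truth$resistant_unique$Hsp90i$up)), universe), 30)
  set.seed(1)
  lib <- gene_set_library(c(
    list(KIN_PLANTED = planted),
    setNames(lapply(1:5, function(i) sample(universe, 30)),
             sprintf("KIN_DECOY%d", 1:5))))
  r <- overrepresentation(query, lib, universe)
  expect_equal(r$term[1], "KIN_PLANTED")
  expect_lt(r$p_value[1], 0.05)
  expect_gt(r$overlap[1], 7)
})
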