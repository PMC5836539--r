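# End-to-end synthetic study: simulate every input, run each analysis
# stage, score calls against planted ground truth, and write deterministic
# result tables plus a run manifest. One root seed drives named substreams
# per stage, so a manifest suffices to reproduce a run byte-for-byte.

.sens_fdr <- function(called, truth) {
  called <- unique(as.character(called)); truth <- unique(as.character(truth))
  tp <- length(intersect(called, truth))
  data.frame(
    n_truth = length(truth), n_called = length(called), n_true_positive = tp,
    sensitivity = if (length(truth)) tp / length(truth) else NA_real_,
    fdr = if (length(called)) 1 - tp / length(called) else NA_real_)
}

# Annotation libraries wired to the planted structure of one synthetic
# study: a planted active kinase whose substrates are drawn from the
# resistant-unique upregulated phosphosites, decoy kinases with random
# substrates, and a kinome/druggable pair covering the planted core
# features. Construction is seeded and part of the study design.
.build_synthetic_libraries <- function(phospho_truth, phospho_ids,
                                       core_features, seed) {
  .with_seed(seed + 557L, {
    substrates_all <- unique(strip_feature_suffix(phospho_ids))
    planted_sites <- phospho_truth$resistant_unique$Hsp90i$up
    planted_sub <- unique(strip_feature_suffix(planted_sites))
    planted_sub <- utils::head(intersect(planted_sub, substrates_all), 30L)
    decoys <- lapply(1:5, function(i) {
      sample(substrates_all, min(30L, length(substrates_all)))
    })
    names(decoys) <- sprintf("KIN_DECOY%d", 1:5)
    terms <- if (length(planted_sub)) {
      c(list(KIN_PLANTED = planted_sub), decoys)
    } else decoys   # nothing planted: the library is all decoys
    ksub <- gene_set_library(terms)

    core <- unique(strip_feature_suffix(core_features))
    other <- sample(setdiff(substrates_all, core),
                    min(20L, length(substrates_all)))
    kinome <- gene_set_library(list(kinome = unique(c(core, other))))
    druggable <- gene_set_library(list(
      druggable_kinome = unique(c(utils::head(core, 1L),
                                  utils::head(other, 5L)))))
    list(kinase_substrate = ksub, kinome = kinome, druggable = druggable)
  })
}

#' Run the full synthetic study end-to-end
#'
#' Simulates TPP, expression (proteome and phosphoproteome), dose-response
#' and co-expression inputs from one seeded configuration, runs every
#' analysis stage, scores each stage against the planted ground truth, and
#' writes all result tables, a scorecard and a run manifest under
#' `out_dir`. Outputs are deterministic: two runs with the same
#' configuration are byte-identical.
#'
#' @param config a [sim_config()]
#' @param out_dir output directory (created if needed); NULL skips writing
#' @param tpp_params hit-calling thresholds, see [tpp_params()]
#' @param p_max,fc_min differential thresholds (Perseus convention)
#' @return invisibly, the result bundle: a list with per-stage results,
#'   `scorecard` and `manifest`
#' @export
run_study <- function(config = sim_config(), out_dir = NULL,
                      tpp_params = meltshift::tpp_params(),
                      p_max = 0.05, fc_min = 1.5) {
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## --- TPP stage -------------------------------------------------------
  tpp <- stage("simulate_tpp", simulate_tpp_experiment(config))
  fits <- stage("tpp_fit", fit_melting_table(tpp$table))
  specs <- standard_comparisons(config$cell_lines, layouts = config$layouts)
  comparisons <- stage("tpp_compare", lapply(specs, function(sp) {
    compare_conditions(fits, sp, params = tpp_params)
  }))
  tpp_summary <- count_significant(comparisons, specs)

  # score the drug-vs-vehicle comparisons against the planted shifted set
  drug_cmp <- which(vapply(specs, function(sp) {
    sp$side_a$treatment == "drug" && sp$side_b$treatment == "vehicle" &&
      sp$side_a$cell_line == sp$side_b$cell_line
  }, TRUE))
  called_shift <- unique(unlist(lapply(comparisons[drug_cmp], function(r) {
    r$feature_id[r$significant]
  })))
  tpp_score <- .sens_fdr(called_shift, tpp$truth$shifted_set)

  ## --- differential proteome stage ------------------------------------
  expr_cfg <- config; expr_cfg$feature_level <- "protein"
  class(expr_cfg) <- "sim_config"
  expr <- stage("simulate_expression", simulate_expression_study(expr_cfg))
  sens_line <- config$cell_lines[1L]; res_line <- config$cell_lines[2L]
  treatments <- c("BRAFi", "Hsp90i", "combo")

  diff_tables <- list()
  unique_up <- list()
  de_called <- character(0); de_truth <- character(0)
  for (trt in treatments) {
    for (cl in config$cell_lines) {
      d <- stage("ttest_differential", ttest_differential(
        expr$table, list(cell_line = cl, treatment = trt),
        list(cell_line = cl, treatment = "DMSO"),
        p_max = p_max, fc_min = fc_min))
      diff_tables[[paste(cl, trt, sep = "_")]] <- d
      tr <- expr$truth$regulated
      for (dir in c("up", "down")) {
        called_ids <- d$feature_id[d$regulated == dir]
        if (length(called_ids)) {
          de_called <- c(de_called, paste(cl, trt, dir, called_ids))
        }
        keys <- tr[tr$cell_line == cl & tr$treatment == trt &
                     tr$direction == dir, "feature_id"]
        if (length(keys)) de_truth <- c(de_truth, paste(cl, trt, dir, keys))
      }
    }
    up_res <- regulated_set(diff_tables[[paste(res_line, trt, sep = "_")]],
                            "up", label = paste(res_line, trt))
    up_sen <- regulated_set(diff_tables[[paste(sens_line, trt, sep = "_")]],
                            "up", label = paste(sens_line, trt))
    unique_up[[trt]] <- subtractive_unique(up_res, up_sen)
  }
  de_score <- .sens_fdr(de_called, de_truth)
  shared_up <- intersect_settings(unique_up)
  core_score <- .sens_fdr(shared_up$shared, expr$truth$core_up_resistant)

  ## --- phosphoproteome + enrichment stage ------------------------------
  phos_cfg <- config; phos_cfg$feature_level <- "phosphopeptide"
  class(phos_cfg) <- "sim_config"
  phos <- stage("simulate_phospho", simulate_expression_study(phos_cfg))
  phos_filtered <- suppressMessages(filter_phospho(phos$table))
  d_res <- stage("phospho_ttest", ttest_differential(
    phos_filtered, list(cell_line = res_line, treatment = "Hsp90i"),
    list(cell_line = res_line, treatment = "DMSO"),
    p_max = p_max, fc_min = fc_min))
  d_sen <- ttest_differential(
    phos_filtered, list(cell_line = sens_line, treatment = "Hsp90i"),
    list(cell_line = sens_line, treatment = "DMSO"),
    p_max = p_max, fc_min = fc_min)
  phos_unique_up <- subtractive_unique(regulated_set(d_res, "up"),
                                       regulated_set(d_sen, "up"))
  libs <- .build_synthetic_libraries(phos$truth,
                                     phos_filtered$features$feature_id,
                                     expr$truth$core_up_resistant,
                                     config$seed)
  query <- suppressWarnings(phosphosite_to_substrate_query(phos_unique_up))
  universe <- unique(strip_feature_suffix(phos_filtered$features$feature_id))
  enr <- stage("enrichment",
               overrepresentation(query, libs$kinase_substrate, universe))
  enr_kept <- kea_filter(enr)
  kin_annot <- annotate_kinases(shared_up$shared, libs$kinome,
                                libs$druggable)

  ## --- synergy stage ----------------------------------------------------
  doses <- stage("simulate_doses", simulate_dose_matrix(config))
  maps <- stage("zip", lapply(doses$matrices, zip_delta))
  syn <- replicate_summary(maps)
  syn_score <- data.frame(planted_delta = config$planted_delta,
                          estimated_delta = syn$summary_delta,
                          abs_error = abs(syn$summary_delta -
                                            config$planted_delta))

  ## --- co-expression stage ---------------------------------------------
  coex <- stage("simulate_coexpr", simulate_coexpression(config))
  corr <- suppressMessages(grouped_correlation(coex$panel,
                                               config$coexpr_genes))
  planted_best <- names(sort(abs(config$group_correlations),
                             decreasing = TRUE))[1L]
  coex_score <- data.frame(planted_top_group = planted_best,
                           called_top_group = corr$group[1L],
                           top_rank_correct = corr$group[1L] == planted_best)

  scorecard <- list(
    tpp_shift = tpp_score,
    differential = de_score,
    shared_upregulated_core = core_score,
    synergy = syn_score,
    coexpression = coex_score)

  manifest <- list(
    package = "meltshift",
    version = as.character(utils::packageVersion("meltshift")),
    seed = config$seed,
    thresholds = c(tpp_params,
                   list(p_max = p_max, fc_min = fc_min,
                        localization_min = 0.75,
                        kea_p_max = 0.05, kea_min_overlap = 7)),
    config = config[setdiff(names(config), "feature_level")])

  bundle <- list(
    tpp = list(fits = fits, comparisons = comparisons,
               summary = tpp_summary, truth = tpp$truth),
    differential = list(tables = diff_tables, unique_up = unique_up,
                        shared_up = shared_up, kinases = kin_annot,
                        truth = expr$truth),
    enrichment = list(all = enr, kept = enr_kept, query_size = length(query)),
    synergy = list(maps = maps, summary = syn),
    coexpression = corr,
    scorecard = scorecard,
    manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(list(
      tpp_fits = fits,
      tpp_summary = tpp_summary,
      tpp_shifts = do.call(rbind, comparisons),
      differential = do.call(rbind, lapply(names(diff_tables), function(nm) {
        cbind(comparison = nm, diff_tables[[nm]])
      })),
      enrichment = enr,
      coexpression = corr,
      synergy_delta = as.data.frame(syn$mean_delta)),
      out_dir)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    jsonlite::write_json(scorecard, file.path(out_dir, "scorecard.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    writeLines(report(bundle), file.path(out_dir, "report.md"))
  }
  invisible(bundle)
}

#' Human-readable study report
#'
#' Markdown summary of a [run_study()] bundle: TPP hit-count table,
#' Venn-style regulated-set sizes, top enrichment terms, the synergy
#' summary and the co-expression ranking, plus the thresholds actually used
#' (read back from the manifest).
#'
#' @param bundle result of [run_study()]
#' @return character vector of markdown lines
#' @export
report <- function(bundle) {
  m <- bundle$manifest
  fmt_tab <- function(df) {
    if (!nrow(df)) return("(no rows)")
    c(paste("|", paste(colnames(df), collapse = " | "), "|"),
      paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
      vapply(seq_len(nrow(df)), function(i) {
        paste("|", paste(vapply(df[i, ], function(v) {
          if (is.numeric(v)) sprintf("%.4g", v) else as.character(v)
        }, ""), collapse = " | "), "|")
      }, ""))
  }
  lines <- c(
    "# Synthetic resistance-proteomics study report",
    "",
    sprintf("Seed %d, package %s %s.", m$seed, m$package, m$version),
    "",
    "## Thermal proteome profiling",
    "",
    if (nrow(bundle$tpp$summary)) fmt_tab(bundle$tpp$summary) else
      "No hits: no comparison yielded significant thermal shifts.",
    "",
    "## Differential expression (resistant-unique upregulation)",
    "")
  for (nm in names(bundle$differential$unique_up)) {
    s <- bundle$differential$unique_up[[nm]]
    lines <- c(lines, sprintf(
      "- %s: %d resistant-unique up (resistant %d, sensitive %d)",
      nm, length(s), attr(s, "n_resistant"), attr(s, "n_sensitive")))
  }
  shared <- bundle$differential$shared_up$shared
  lines <- c(lines, "",
             sprintf("Shared across settings: %s",
                     if (length(shared)) paste(shared, collapse = ", ")
                     else "none"),
             sprintf("Kinases among shared: %s; druggable: %s",
                     if (length(bundle$differential$kinases$kinases))
                       paste(bundle$differential$kinases$kinases,
                             collapse = ", ") else "none",
                     if (length(bundle$differential$kinases$druggable_kinases))
                       paste(bundle$differential$kinases$druggable_kinases,
                             collapse = ", ") else "none"),
             "",
             "## Kinase-substrate enrichment",
             "")
  if (nrow(bundle$enrichment$kept)) {
    lines <- c(lines, fmt_tab(utils::head(
      bundle$enrichment$kept[, c("term", "overlap", "p_value", "p_adj")],
      10L)))
  } else {
    lines <- c(lines, "No terms pass the reporting filter.")
  }
  lines <- c(lines, "",
             "## Drug synergy (ZIP)",
             "",
             sprintf("Mean delta over combination wells: %+.4f (replicate SD %.4f)",
                     bundle$synergy$summary$summary_delta,
                     bundle$synergy$summary$summary_sd),
             "",
             "## Co-expression ranking",
             "",
             fmt_tab(bundle$coexpression),
             "",
             "## Thresholds used",
             "",
             vapply(names(m$thresholds), function(k) {
               sprintf("- %s = %s", k, format(m$thresholds[[k]]))
             }, ""))
  lines
}
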