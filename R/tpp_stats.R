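# Significance calling for melting-point shifts between paired condition
# sets. The hit rules codify the published replicate-concordance criteria:
# per-pair p-value thresholds with the stricter one applied to the
# larger-|dTm| pair, same-sign dTm across replicate pairs, the drug-induced
# shift exceeding the vehicle-vs-vehicle replicate instability, and
# curve-quality gates on both sides.

#' Default thresholds for thermal-shift hit calling
#'
#' @param p_strict p-value threshold applied to the replicate pair with the
#'   larger |dTm| (default 0.05)
#' @param p_loose p-value threshold for the other pair (default 0.1)
#' @param r2_min minimum sigmoid fit R^2 on both sides (default 0.8)
#' @param plateau_max maximum vehicle-side plateau (default 0.3)
#' @param slope_max maximum (i.e. least negative allowed) steepest slope in
#'   1/degC; curves must melt at least this steeply (default -0.06)
#' @return list of thresholds
#' @export
tpp_params <- function(p_strict = 0.05, p_loose = 0.1, r2_min = 0.8,
                       plateau_max = 0.3, slope_max = -0.06) {
  list(p_strict = p_strict, p_loose = p_loose, r2_min = r2_min,
       plateau_max = plateau_max, slope_max = slope_max)
}

#' Specify one paired thermal-stability comparison
#'
#' A side is a condition key (cell line, treatment, layout); replicate
#' pairing links side-A replicates to side-B replicates. The same machinery
#' covers drug-vs-vehicle within one cell line and cell-line-vs-cell-line
#' at matched treatment.
#'
#' @param label human-readable comparison label (used in summaries)
#' @param side_a,side_b lists with `cell_line`, `treatment`, `layout`
#' @param pairing list of `c(a_replicate, b_replicate)` pairs (>= 2 for hit
#'   calling)
#' @return object of class `comparison_spec`
#' @export
comparison_spec <- function(label, side_a, side_b,
                            pairing = list(c(1L, 1L), c(2L, 2L))) {
  need <- c("cell_line", "treatment", "layout")
  stopifnot(all(need %in% names(side_a)), all(need %in% names(side_b)))
  if (length(pairing) < 2L) {
    stop("at least two replicate pairs are required for hit calling")
  }
  structure(list(label = label, side_a = side_a, side_b = side_b,
                 pairing = pairing),
            class = "comparison_spec")
}

#' Curve-quality gate for one fit pair
#'
#' Pass requires: both fits converged with a defined Tm, R^2 at or above
#' `r2_min` on both sides, vehicle-side plateau below `plateau_max`, and a
#' steepest slope at or below `slope_max` on both sides. Reason codes
#' enumerate exactly which rule failed.
#'
#' @param fit_a,fit_b one-row data.frames (or lists) carrying `r2`,
#'   `plateau`, `min_slope`, `tm`, `converged`; `fit_b` is the
#'   vehicle/reference side whose plateau is gated
#' @param params a [tpp_params()] list
#' @return list with `pass` (logical) and `reasons` (character vector drawn
#'   from NOMELT, R2, PLATEAU, SLOPE; empty when passing)
#' @export
qc_filter <- function(fit_a, fit_b, params = tpp_params()) {
  reasons <- character(0)
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged) ||
      is.na(fit_a$tm) || is.na(fit_b$tm)) {
    reasons <- c(reasons, "NOMELT")
  } else {
    if (fit_a$r2 < params$r2_min || fit_b$r2 < params$r2_min) {
      reasons <- c(reasons, "R2")
    }
    if (fit_b$plateau >= params$plateau_max) reasons <- c(reasons, "PLATEAU")
    if (fit_a$min_slope > params$slope_max ||
        fit_b$min_slope > params$slope_max) {
      reasons <- c(reasons, "SLOPE")
    }
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

# Two-sided p-values from a robust z-score against the empirical dTm
# distribution, with the spread estimated separately on each side of the
# median from the 15.87 / 84.13 percentiles (the +/- 1 SD quantiles of a
# Gaussian). Side-specific spread keeps one heavy tail from masking the
# other.
.robust_z_p <- function(delta) {
  ok <- !is.na(delta)
  p <- rep(NA_real_, length(delta))
  if (sum(ok) < 10L) return(p)
  d <- delta[ok]
  med <- stats::median(d)
  s_left <- med - stats::quantile(d, 0.1587, names = FALSE)
  s_right <- stats::quantile(d, 0.8413, names = FALSE) - med
  eps <- 1e-8
  s_left <- max(s_left, eps); s_right <- max(s_right, eps)
  z <- ifelse(delta < med, (delta - med) / s_left, (delta - med) / s_right)
  2 * stats::pnorm(-abs(z))
}

.pick_fits <- function(fits, side, replicate) {
  fits[fits$cell_line == side$cell_line & fits$treatment == side$treatment &
         fits$layout == side$layout & fits$replicate == replicate, ,
       drop = FALSE]
}

#' Call thermal-stability shifts between two condition sets
#'
#' Computes per-replicate-pair delta-Tm (side A minus side B), per-pair
#' robust-z p-values against the empirical delta-Tm distribution of all
#' QC-passing features, BH-adjusted p per pair, and a significance verdict
#' per the replicate-concordance hit rules: (i) p below `p_strict` for the
#' larger-|dTm| pair and below `p_loose` for the other; (ii) all pair dTm of
#' the same sign; (iii) the smallest |dTm| across pairs exceeding the
#' reference-side replicate instability |Tm(B, rep 1) - Tm(B, rep 2)|;
#' (iv) the QC gate on every curve. The full feature table is returned with
#' reason codes; nothing is silently dropped.
#'
#' @param fits fit table from [fit_melting_table()] covering both sides
#' @param spec a [comparison_spec()]
#' @param params a [tpp_params()] list
#' @return data.frame, one row per feature, with per-pair `dtm_<k>`,
#'   `p_<k>`, `padj_<k>` columns plus `mean_dtm`, `same_sign`, `qc_pass`,
#'   `reasons`, `stability_dtm`, `significant`, `status`
#'   (tested / unpaired / excluded)
#' @export
compare_conditions <- function(fits, spec, params = tpp_params()) {
  stopifnot(inherits(spec, "comparison_spec"))
  n_pairs <- length(spec$pairing)

  pair_tabs <- lapply(spec$pairing, function(pr) {
    fa <- .pick_fits(fits, spec$side_a, pr[1L])
    fb <- .pick_fits(fits, spec$side_b, pr[2L])
    merge(fa, fb, by = "feature_id", suffixes = c("_a", "_b"))
  })
  all_ids <- sort(unique(unlist(c(
    lapply(spec$pairing, function(pr) {
      c(.pick_fits(fits, spec$side_a, pr[1L])$feature_id,
        .pick_fits(fits, spec$side_b, pr[2L])$feature_id)
    })))))
  paired_ids <- Reduce(intersect, lapply(pair_tabs, `[[`, "feature_id"))

  res <- data.frame(feature_id = all_ids, stringsAsFactors = FALSE)
  res$status <- ifelse(all_ids %in% paired_ids, "tested", "unpaired")

  # reference-side replicate instability, from the first two B replicates
  b_reps <- unique(vapply(spec$pairing, `[[`, 0L, 2L))
  stab <- rep(NA_real_, length(all_ids))
  if (length(b_reps) >= 2L) {
    fb1 <- .pick_fits(fits, spec$side_b, b_reps[1L])
    fb2 <- .pick_fits(fits, spec$side_b, b_reps[2L])
    m <- merge(fb1[, c("feature_id", "tm")], fb2[, c("feature_id", "tm")],
               by = "feature_id")
    stab[match(m$feature_id, all_ids)] <- abs(m$tm.x - m$tm.y)
  }
  res$stability_dtm <- stab

  qc_all <- rep(TRUE, length(all_ids))
  reasons_all <- vector("list", length(all_ids))
  dtm_mat <- matrix(NA_real_, nrow = length(all_ids), ncol = n_pairs)
  p_mat <- matrix(NA_real_, nrow = length(all_ids), ncol = n_pairs)
  padj_mat <- matrix(NA_real_, nrow = length(all_ids), ncol = n_pairs)

  for (k in seq_len(n_pairs)) {
    tb <- pair_tabs[[k]]
    idx <- match(tb$feature_id, all_ids)
    qc <- lapply(seq_len(nrow(tb)), function(i) {
      qc_filter(list(converged = tb$converged_a[i], tm = tb$tm_a[i],
                     r2 = tb$r2_a[i], plateau = tb$plateau_a[i],
                     min_slope = tb$min_slope_a[i]),
                list(converged = tb$converged_b[i], tm = tb$tm_b[i],
                     r2 = tb$r2_b[i], plateau = tb$plateau_b[i],
                     min_slope = tb$min_slope_b[i]),
                params)
    })
    pass <- vapply(qc, `[[`, TRUE, "pass")
    dtm <- tb$tm_a - tb$tm_b
    # robust z computed on the QC-passing empirical distribution only
    p <- .robust_z_p(ifelse(pass, dtm, NA))
    dtm_mat[idx, k] <- dtm
    p_mat[idx, k] <- p
    padj_mat[idx, k] <- stats::p.adjust(p, method = "BH")
    qc_all[idx] <- qc_all[idx] & pass
    for (i in seq_len(nrow(tb))) {
      reasons_all[[idx[i]]] <- union(reasons_all[[idx[i]]],
                                     qc[[i]]$reasons)
    }
  }
  qc_all[res$status != "tested"] <- FALSE

  for (k in seq_len(n_pairs)) {
    res[[paste0("dtm_", k)]] <- dtm_mat[, k]
    res[[paste0("p_", k)]] <- p_mat[, k]
    res[[paste0("padj_", k)]] <- padj_mat[, k]
  }
  res$mean_dtm <- rowMeans(dtm_mat)
  res$qc_pass <- qc_all

  same_sign <- apply(dtm_mat, 1L, function(d) {
    if (any(is.na(d))) return(NA)
    all(d > 0) || all(d < 0)
  })
  res$same_sign <- same_sign

  p_rule <- rep(FALSE, length(all_ids))
  for (i in seq_len(length(all_ids))) {
    d <- dtm_mat[i, ]; p <- p_mat[i, ]
    if (any(is.na(d)) || any(is.na(p))) next
    ord <- order(abs(d), decreasing = TRUE)
    thr <- c(params$p_strict, rep(params$p_loose, n_pairs - 1L))
    p_rule[i] <- all(p[ord] < thr)
  }
  min_abs_dtm <- apply(abs(dtm_mat), 1L, min)
  stab_rule <- !is.na(res$stability_dtm) & !is.na(min_abs_dtm) &
    min_abs_dtm > res$stability_dtm

  res$significant <- res$qc_pass & !is.na(same_sign) & same_sign &
    p_rule & stab_rule
  res$reasons <- vapply(seq_along(all_ids), function(i) {
    rs <- reasons_all[[i]]
    if (res$status[i] == "unpaired") rs <- union(rs, "UNPAIRED")
    if (res$qc_pass[i]) {
      if (isFALSE(same_sign[i])) rs <- union(rs, "SIGN")
      if (!p_rule[i]) rs <- union(rs, "PVALUE")
      if (!stab_rule[i]) rs <- union(rs, "STABILITY")
    }
    if (res$significant[i]) rs <- character(0)
    paste(rs, collapse = ";")
  }, "")
  res$label <- spec$label
  res
}

#' Summarize hit counts across comparisons
#'
#' One row per (layout, comparison label) with the number of
#' replicate-concordant significant features, plus a secondary union count
#' (features passing the per-pair p threshold and QC in at least one pair).
#'
#' @param results named list of [compare_conditions()] tables; names are
#'   ignored, labels come from the tables
#' @param specs list of the matching [comparison_spec()] objects (for
#'   layout labels)
#' @return data.frame with `layout`, `comparison`, `n_significant`,
#'   `n_union`
#' @export
count_significant <- function(results, specs) {
  if (!length(results)) {
    return(data.frame(layout = character(0), comparison = character(0),
                      n_significant = integer(0), n_union = integer(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    spec <- specs[[i]]
    p_cols <- grep("^p_[0-9]+$", colnames(r))
    union_n <- sum(r$qc_pass &
                     apply(r[, p_cols, drop = FALSE] < 0.05, 1L, any),
                   na.rm = TRUE)
    data.frame(layout = spec$side_a$layout,
               comparison = spec$label,
               n_significant = sum(r$significant, na.rm = TRUE),
               n_union = union_n, stringsAsFactors = FALSE)
  }))
}

#' The eight standard comparison specs of a two-line, two-layout TPP study
#'
#' Per layout: each cell line drug vs vehicle, resistant vehicle vs
#' sensitive vehicle, and resistant drug vs sensitive drug.
#'
#' @param cell_lines two cell-line names (sensitive first)
#' @param layouts layout names (default lysate and intact)
#' @param drug_name label used for the drug in comparison names
#' @return list of [comparison_spec()]
#' @export
standard_comparisons <- function(cell_lines, layouts = c("lysate", "intact"),
                                 drug_name = "Hsp90i") {
  sens <- cell_lines[1L]; res <- cell_lines[2L]
  out <- list()
  for (lay in layouts) {
    side <- function(cl, trt) list(cell_line = cl, treatment = trt,
                                   layout = lay)
    out <- c(out, list(
      comparison_spec(sprintf("%s %s/DMSO", sens, drug_name),
                      side(sens, "drug"), side(sens, "vehicle")),
      comparison_spec(sprintf("%s %s/DMSO", res, drug_name),
                      side(res, "drug"), side(res, "vehicle")),
      comparison_spec(sprintf("%s DMSO/%s DMSO", res, sens),
                      side(res, "vehicle"), side(sens, "vehicle")),
      comparison_spec(sprintf("%s %s/%s %s", res, drug_name, sens, drug_name),
                      side(res, "drug"), side(sens, "drug"))))
  }
  out
}
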