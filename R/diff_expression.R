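# Two-group differential analysis of label-free (phospho)proteomes in the
# Perseus convention: Student's two-sample t-test on log2 intensities, raw
# p-value threshold plus a symmetric fold-change cutoff expressed on the
# +/-1.5 ratio scale, no imputation. Set algebra on the resulting regulated
# sets isolates resistance-unique candidates.

#' Two-sample t-test differential analysis
#'
#' Tests each feature between two sample groups on the log2 scale. The fold
#' change is the linear-scale ratio of group means with the signed
#' convention: ratios >= 1 are reported as-is, ratios < 1 as the negative
#' reciprocal, so a halving appears as -2. Regulation flags apply the raw
#' p-value and fold-change cutoffs; a BH-adjusted p is reported alongside
#' but takes no part in the flags.
#'
#' @param tab an `expression_table`
#' @param group_a,group_b lists with `cell_line` and `treatment` selecting
#'   the two sample groups (A is the numerator of the fold change)
#' @param p_max raw p-value threshold (default 0.05)
#' @param fc_min fold-change magnitude threshold on the signed ratio scale
#'   (default 1.5)
#' @param var_equal TRUE for Student's equal-variance test (the Perseus
#'   default); FALSE for Welch
#' @return data.frame: `feature_id`, `n_a`, `n_b`, `mean_a`, `mean_b` (log2),
#'   `fold_change` (signed ratio), `t_stat`, `p_value`, `p_adj`, `regulated`
#'   (up/down/none), `tested` plus `reason` for untested rows
#' @export
ttest_differential <- function(tab, group_a, group_b, p_max = 0.05,
                               fc_min = 1.5, var_equal = TRUE) {
  stopifnot(inherits(tab, "expression_table"))
  sel <- function(g) {
    which(tab$samples$cell_line == g$cell_line &
            tab$samples$treatment == g$treatment)
  }
  ia <- sel(group_a); ib <- sel(group_b)
  if (!length(ia) || !length(ib)) stop("empty sample group")
  la <- log2(tab$intensities[, ia, drop = FALSE])
  lb <- log2(tab$intensities[, ib, drop = FALSE])

  n <- nrow(tab$features)
  out <- data.frame(feature_id = tab$features$feature_id,
                    n_a = NA_integer_, n_b = NA_integer_,
                    mean_a = NA_real_, mean_b = NA_real_,
                    fold_change = NA_real_, t_stat = NA_real_,
                    p_value = NA_real_, p_adj = NA_real_,
                    regulated = "none", tested = FALSE, reason = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    xa <- la[i, ]; xb <- lb[i, ]
    xa <- xa[is.finite(xa)]; xb <- xb[is.finite(xb)]
    out$n_a[i] <- length(xa); out$n_b[i] <- length(xb)
    if (length(xa) < 2L || length(xb) < 2L) {
      out$reason[i] <- "fewer than 2 valid values in a group"
      next
    }
    out$mean_a[i] <- mean(xa); out$mean_b[i] <- mean(xb)
    ratio <- 2^(out$mean_a[i] - out$mean_b[i])
    out$fold_change[i] <- if (ratio >= 1) ratio else -1 / ratio
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      out$t_stat[i] <- if (mean(xa) == mean(xb)) 0 else Inf
      out$p_value[i] <- if (mean(xa) == mean(xb)) 1 else 0
    } else {
      tt <- stats::t.test(xa, xb, var.equal = var_equal)
      out$t_stat[i] <- unname(tt$statistic)
      out$p_value[i] <- tt$p.value
    }
    out$tested[i] <- TRUE
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$regulated <- ifelse(
    out$tested & out$p_value < p_max & out$fold_change >= fc_min, "up",
    ifelse(out$tested & out$p_value < p_max & out$fold_change <= -fc_min,
           "down", "none"))
  out
}

#' Filter phosphopeptides by localization probability
#'
#' Retains rows whose phosphosite localization probability is at least 0.75
#' (inclusive). Applying the filter to protein rows is an error: proteins
#' carry no localization concept.
#'
#' @param tab an `expression_table` of phosphopeptides
#' @param min_probability inclusive threshold (default 0.75)
#' @return filtered `expression_table`; the number of removed rows is
#'   reported via message and stored in the `n_removed` attribute
#' @export
filter_phospho <- function(tab, min_probability = 0.75) {
  stopifnot(inherits(tab, "expression_table"))
  if (any(tab$features$feature_level != "phosphopeptide")) {
    stop("filter_phospho applies only to phosphopeptide tables")
  }
  keep <- tab$features$localization_probability >= min_probability
  removed <- sum(!keep)
  message(sprintf("filter_phospho: removed %d / %d rows below %.2f",
                  removed, length(keep), min_probability))
  out <- expression_table(tab$features[keep, , drop = FALSE],
                          tab$intensities[keep, , drop = FALSE],
                          tab$samples[, c("cell_line", "treatment",
                                          "replicate")])
  attr(out, "n_removed") <- removed
  out
}

#' Extract a regulated feature set from a differential table
#'
#' @param diff result of [ttest_differential()]
#' @param direction `"up"` or `"down"`
#' @param label comparison label carried on the result
#' @return object of class `regulated_set`: character feature ids with
#'   `direction` and `label` attributes
#' @export
regulated_set <- function(diff, direction = c("up", "down"), label = "") {
  direction <- match.arg(direction)
  ids <- diff$feature_id[diff$regulated == direction]
  structure(sort(unique(ids)), direction = direction, label = label,
            class = "regulated_set")
}

#' Resistance-unique features by subtraction
#'
#' Removes the regulated entries of the sensitive line from those of the
#' resistant line (set difference resistant \ sensitive), isolating
#' candidates unique to the resistant response. Both sets must carry the
#' same regulation direction.
#'
#' @param set_resistant,set_sensitive `regulated_set` objects (or plain
#'   character vectors of the same direction)
#' @return `regulated_set` of the difference, with `n_resistant` and
#'   `n_sensitive` provenance attributes
#' @export
subtractive_unique <- function(set_resistant, set_sensitive) {
  da <- attr(set_resistant, "direction"); db <- attr(set_sensitive, "direction")
  if (!is.null(da) && !is.null(db) && !identical(da, db)) {
    stop(sprintf("direction mismatch: %s vs %s", da, db))
  }
  out <- sort(setdiff(as.character(set_resistant),
                      as.character(set_sensitive)))
  structure(out, direction = da,
            label = attr(set_resistant, "label"),
            n_resistant = length(set_resistant),
            n_sensitive = length(set_sensitive),
            class = "regulated_set")
}

#' Intersect resistance-unique sets across treatment settings
#'
#' Features shared by every setting (e.g. unique to the resistant line
#' under BRAFi, Hsp90i and the combination alike), with a per-set
#' membership table for Venn-style reporting.
#'
#' @param sets named list of two or more feature-id vectors
#' @return list with `shared` (sorted character vector, possibly empty) and
#'   `membership` (data.frame, one row per feature in the union, one
#'   logical column per set)
#' @export
intersect_settings <- function(sets) {
  if (length(sets) < 2L) stop("at least two sets are required")
  sets <- lapply(sets, as.character)
  shared <- sort(Reduce(intersect, sets))
  universe <- sort(unique(unlist(sets)))
  membership <- data.frame(feature_id = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) membership[[nm]] <- universe %in% sets[[nm]]
  list(shared = shared, membership = membership)
}

#' Annotate a feature set against kinome and druggable-kinome libraries
#'
#' @param set character feature ids (phosphosite suffixes are stripped
#'   before matching)
#' @param kinome `gene_set_library` whose union of members defines the
#'   kinome
#' @param druggable `gene_set_library` whose union defines the druggable
#'   kinome; defaults to an empty library
#' @return list with `kinases` and `druggable_kinases` (sorted character
#'   vectors) and `sources` (names of the libraries' terms consulted)
#' @export
annotate_kinases <- function(set, kinome, druggable = NULL) {
  if (!length(kinome)) stop("empty kinome library")
  genes <- unique(strip_feature_suffix(as.character(set)))
  kin_members <- unique(unlist(kinome))
  drug_members <- if (is.null(druggable)) character(0) else
    unique(unlist(druggable))
  kin <- sort(intersect(genes, kin_members))
  drg <- sort(intersect(kin, drug_members))
  list(kinases = kin, druggable_kinases = drg,
       sources = list(kinome = names(kinome),
                      druggable = if (is.null(druggable)) character(0)
                                  else names(druggable)))
}
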