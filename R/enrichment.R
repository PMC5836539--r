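# Over-representation of annotation terms in feature sets: kinase-substrate
# enrichment for phosphosite-derived sets and TF-target enrichment for
# protein sets, one hypergeometric engine for both. The universe defaults to
# what was quantified in the experiment, not the genome.

#' Hypergeometric over-representation of library terms in a query set
#'
#' Per term, the upper-tail hypergeometric probability of drawing at least
#' the observed overlap when `|query|` features are sampled without
#' replacement from the universe. Terms are intersected with the universe
#' before testing; BH adjustment is across terms; rows are sorted by
#' (p, -overlap, term) for deterministic output.
#'
#' @param query character feature ids; must be a subset of `universe`
#' @param library a `gene_set_library`
#' @param universe character vector of all testable features (background)
#' @return data.frame: `term`, `overlap` (intersected genes), `set_size`,
#'   `term_size` (within the universe), `universe_size`, `p_value`, `p_adj`
#' @export
overrepresentation <- function(query, library, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  off <- setdiff(query, universe)
  if (length(off)) {
    stop("query features outside the universe: ",
         paste(utils::head(off, 5L), collapse = ", "),
         if (length(off) > 5L) sprintf(" (and %d more)", length(off) - 5L))
  }
  n_u <- length(universe); n_q <- length(query)
  rows <- lapply(names(library), function(tm) {
    members <- intersect(library[[tm]], universe)
    k <- length(intersect(query, members))
    m <- length(members)
    # P(X >= k) for X ~ Hypergeometric(m, n_u - m, n_q)
    p <- stats::phyper(k - 1L, m, n_u - m, n_q, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, set_size = n_q, term_size = m,
               universe_size = n_u, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term = character(0), overlap = integer(0),
                      set_size = integer(0), term_size = integer(0),
                      universe_size = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  res[order(res$p_value, -res$overlap, res$term), , drop = FALSE]
}

#' Kinase-substrate enrichment reporting filter
#'
#' Keeps terms with raw p-value below 0.05 and strictly more than 7
#' intersected genes — the reporting rule used for kinase triage.
#'
#' @param results data.frame from [overrepresentation()]
#' @param p_max raw p-value cutoff (default 0.05, exclusive)
#' @param min_overlap overlap cutoff (default 7, strictly greater than)
#' @return filtered data.frame with a `passes_filter` column (all TRUE)
#' @export
kea_filter <- function(results, p_max = 0.05, min_overlap = 7L) {
  keep <- results$p_value < p_max & results$overlap > min_overlap
  out <- results[keep, , drop = FALSE]
  if (nrow(out)) out$passes_filter <- TRUE
  out
}

#' Collapse a phosphosite set to a substrate-protein query
#'
#' `PROT1_pS10` and `PROT1_pT20` both map to `PROT1`; one entry per
#' substrate protein regardless of site multiplicity. Ids without a
#' parseable `_p[STY]<pos>` suffix are skipped with a warning.
#'
#' @param phospho_set character phosphosite ids
#' @return sorted, deduplicated character vector of protein ids, with the
#'   skipped ids in the `skipped` attribute
#' @export
phosphosite_to_substrate_query <- function(phospho_set) {
  ids <- as.character(phospho_set)
  ok <- grepl("_p[STY][0-9]+$", ids)
  if (any(!ok)) {
    warning(sprintf("%d id(s) without a phosphosite suffix skipped: %s",
                    sum(!ok), paste(utils::head(ids[!ok], 3L),
                                    collapse = ", ")))
  }
  out <- sort(unique(sub("_p[STY][0-9]+$", "", ids[ok])))
  attr(out, "skipped") <- ids[!ok]
  out
}
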