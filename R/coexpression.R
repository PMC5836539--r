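# Grouped two-gene co-expression ranking: which sample group (cancer type,
# cohort) shows the strongest, most significant Pearson correlation between
# two genes' expression.

#' Per-group Pearson correlation of two genes, ranked
#'
#' Computes Pearson r and its two-sided p-value within each sample group,
#' BH-adjusts across groups, and ranks by (adjusted p, -r). Expression is
#' expected on the log2 scale; raw TPM can be transformed first with
#' `log2(TPM + 1)`. Groups below `min_n` are excluded with a notice;
#' zero-variance genes make r undefined for that group, flagged rather than
#' dropped.
#'
#' @param panel data.frame with a `group` column and two gene columns
#' @param genes character(2): the gene column names
#' @param min_n minimum group size (default 10)
#' @param log_transform apply `log2(x + 1)` to the gene columns first
#'   (default FALSE: input already log scale)
#' @return data.frame ranked best-first: `group`, `n`, `pearson_r`,
#'   `p_value`, `p_adj`, `flag` (`""`, `"zero_variance"`, or
#'   `"too_small"`; flagged groups sort last)
#' @export
grouped_correlation <- function(panel, genes, min_n = 10L,
                                log_transform = FALSE) {
  stopifnot(all(c("group", genes) %in% colnames(panel)),
            length(genes) == 2L)
  groups <- unique(panel$group)
  if (length(groups) < 2L) stop("at least two groups are required")
  rows <- lapply(groups, function(g) {
    sub <- panel[panel$group == g, , drop = FALSE]
    x <- sub[[genes[1L]]]; y <- sub[[genes[2L]]]
    if (log_transform) { x <- log2(x + 1); y <- log2(y + 1) }
    n <- sum(is.finite(x) & is.finite(y))
    out <- data.frame(group = g, n = n, pearson_r = NA_real_,
                      p_value = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    if (n < min_n) { out$flag <- "too_small"; return(out) }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      out$flag <- "zero_variance"; return(out)
    }
    r <- stats::cor(x, y)
    out$pearson_r <- r
    out$p_value <- if (abs(r) >= 1) 0 else
      stats::cor.test(x, y)$p.value
    out
  })
  res <- do.call(rbind, rows)
  excluded <- res$flag == "too_small"
  if (any(excluded)) {
    message("groups below min_n excluded from ranking: ",
            paste(res$group[excluded], collapse = ", "))
  }
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  ord <- order(res$flag != "", res$p_adj, -res$pearson_r)
  res <- res[ord, c("group", "n", "pearson_r", "p_value", "p_adj", "flag")]
  rownames(res) <- NULL
  res
}
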