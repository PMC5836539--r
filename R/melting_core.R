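#' Three-parameter melting sigmoid
#'
#' Fraction of protein remaining soluble at temperature `T` under the
#' chaperone-denaturation model used throughout thermal proteome profiling:
#' \deqn{f(T) = \frac{1 - p}{1 + e^{-(a/T - b)}} + p}
#' where `p` is the high-temperature plateau (fraction never denatured), and
#' `a`, `b` shape the transition. With `p = 0` the curve crosses 0.5 at
#' `T = a/b`.
#'
#' @param temp temperature(s) in degrees Celsius (> 0)
#' @param p plateau in `[0, 1)`
#' @param a,b sigmoid shape parameters (`a` has units of degC, `b` unitless)
#' @return fraction non-denatured, same length as `temp`
#' @export
melt_sigmoid <- function(temp, p, a, b) {
  (1 - p) / (1 + exp(-(a / temp - b))) + p
}

#' Analytic slope of the melting sigmoid
#'
#' d f / dT; negative throughout for a melter (`a > 0`).
#'
#' @inheritParams melt_sigmoid
#' @return slope in 1/degC
#' @export
melt_sigmoid_slope <- function(temp, p, a, b) {
  u <- a / temp - b
  s <- 1 / (1 + exp(-u))          # logistic(u)
  -(1 - p) * s * (1 - s) * a / temp^2
}

#' Melting point from fitted sigmoid parameters
#'
#' Solves `f(Tm) = 0.5` in closed form:
#' `Tm = a / (b - ln(0.5 / (0.5 - p)))`. Undefined (NA) when the curve never
#' crosses 0.5 (`p >= 0.5`), when the root is non-physical (denominator
#' `<= 0`), or when the root falls outside an extrapolation-guard window
#' around the measured temperature range (roots far beyond the gradient are
#' fit artifacts, not measurements).
#'
#' @param p,a,b fitted sigmoid parameters
#' @param t_range optional numeric range (min, max) of measured temperatures;
#'   when supplied, Tm outside `[min - guard, max + guard]` is rejected
#' @param guard width of the extrapolation guard in degC (default 5)
#' @return melting point in degC, or `NA_real_` when undefined
#' @export
compute_tm <- function(p, a, b, t_range = NULL, guard = 5) {
  if (is.na(p) || is.na(a) || is.na(b)) return(NA_real_)
  if (p >= 0.5) return(NA_real_)
  denom <- b - log(0.5 / (0.5 - p))
  if (!is.finite(denom) || denom <= 0) return(NA_real_)
  tm <- a / denom
  if (!is.null(t_range)) {
    lo <- min(t_range) - guard
    hi <- max(t_range) + guard
    if (tm < lo || tm > hi) return(NA_real_)
  }
  tm
}

#' Normalize a raw reporter-intensity profile to the lowest temperature
#'
#' Divides all ten channels by the lowest-temperature channel so that the
#' profile starts at exactly 1 (fold change relative to the non-denaturing
#' reference). A missing or zero reference channel makes the whole profile
#' unusable: zero at higher temperatures is a legitimate fully-denatured
#' measurement, but a zero reference admits no relative scale.
#'
#' @param raw numeric vector of raw intensities, ordered by ascending
#'   temperature; `NA` encodes an absent channel
#' @return list with `y` (normalized profile, `y[1] == 1`) and `usable`
#'   (FALSE when the reference channel is absent or zero, in which case
#'   `y` is all-NA)
#' @export
normalize_profile <- function(raw) {
  raw <- as.numeric(raw)
  if (length(raw) < 2L) stop("profile needs at least two channels")
  ref <- raw[1L]
  if (is.na(ref) || ref <= 0) {
    return(list(y = rep(NA_real_, length(raw)), usable = FALSE))
  }
  list(y = raw / ref, usable = TRUE)
}

# Deterministic start points for the sigmoid fit. Tm is seeded from the
# half-decay crossing of the observed profile; restarts perturb the slope
# parameter and the Tm seed with fixed factors (no RNG, so fits are
# reproducible and peptide/protein modes agree exactly on identical input).
.melt_fit_starts <- function(temp, y) {
  ymin <- max(min(y, na.rm = TRUE), 0)
  p0 <- min(ymin, 0.39)
  half <- (1 + p0) / 2
  below <- which(y <= half)
  tm_guess <- if (length(below)) temp[below[1L]] else max(temp)
  tm_guess <- min(max(tm_guess, min(temp) + 1), max(temp))
  starts <- list()
  for (fac in c(1, 0.95, 1.05)) {
    for (b0 in c(10, 6, 15)) {
      starts[[length(starts) + 1L]] <-
        c(p = p0, a = b0 * tm_guess * fac, b = b0)
    }
  }
  starts
}

#' Fit the three-parameter melting sigmoid to one profile
#'
#' Bounded least squares (Levenberg-Marquardt) of `melt_sigmoid` against a
#' normalized profile, with deterministic multi-start initialization. Absent
#' channels are omitted from the loss; no imputation. The plateau is bounded
#' to `[0, 0.4]` during fitting so curves stay physically meaningful
#' (downstream QC applies the stricter `plateau < 0.3` rule).
#'
#' @param temp numeric vector of temperatures (degC, strictly increasing)
#' @param y normalized relative abundances (`y[1]` typically 1); `NA` marks
#'   absent channels
#' @param min_channels minimum number of observed channels required (default 8)
#' @param guard extrapolation guard passed to [compute_tm()]
#' @return object of class `melting_fit`: list with elements `p`, `a`, `b`,
#'   `tm`, `r2`, `min_slope`, `rss`, `converged`, `status`
#'   (`"ok"`, `"flat"`, `"nonconverged"`, or `"unusable"`). Non-converged
#'   fits carry `NA` parameters, never fabricated values.
#' @export
fit_melting_curve <- function(temp, y, min_channels = 8L, guard = 5) {
  stopifnot(length(temp) == length(y))
  out <- structure(
    list(p = NA_real_, a = NA_real_, b = NA_real_, tm = NA_real_,
         r2 = NA_real_, min_slope = NA_real_, rss = NA_real_,
         converged = FALSE, status = "unusable"),
    class = "melting_fit")
  keep <- !is.na(y)
  if (sum(keep) < min_channels) return(out)
  tt <- temp[keep]
  yy <- y[keep]
  tss <- sum((yy - mean(yy))^2)
  if (tss < 1e-12) {
    # profile carries no decay signal; a sigmoid is unidentifiable
    out$status <- "flat"
    return(out)
  }
  resid_fun <- function(par) {
    yy - ((1 - par[1L]) / (1 + exp(-(par[2L] / tt - par[3L]))) + par[1L])
  }
  best <- NULL
  starts <- .melt_fit_starts(tt, yy)
  for (si in seq_along(starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[si]],
        lower = c(p = 0, a = 1e-6, b = 1e-6),
        upper = c(p = 0.4, a = 1e6, b = 100),
        fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(coef = fit$par, rss = rss)
    }
    # remaining starts only matter while the residual still looks like a
    # local optimum rather than measurement noise
    if (best$rss < 1e-12) break
    if (si >= 3L && best$rss / tss < 1e-8) break
  }
  if (is.null(best)) {
    out$status <- "nonconverged"
    return(out)
  }
  cf <- best$coef
  out$p <- unname(cf["p"]); out$a <- unname(cf["a"]); out$b <- unname(cf["b"])
  out$rss <- best$rss
  out$r2 <- 1 - best$rss / tss
  grid <- seq(min(tt), max(tt), length.out = 200L)
  out$min_slope <- min(melt_sigmoid_slope(grid, out$p, out$a, out$b))
  out$tm <- compute_tm(out$p, out$a, out$b, t_range = range(tt), guard = guard)
  out$converged <- TRUE
  out$status <- "ok"
  out
}

#' @export
print.melting_fit <- function(x, ...) {
  cat(sprintf(
    "melting_fit: status=%s p=%.3f a=%.1f b=%.2f Tm=%s r2=%s\n",
    x$status, x$p, x$a, x$b,
    ifelse(is.na(x$tm), "NA", sprintf("%.2f", x$tm)),
    ifelse(is.na(x$r2), "NA", sprintf("%.3f", x$r2))))
  invisible(x)
}

#' Aggregate peptide profiles to a protein profile
#'
#' Channel-wise median of the normalized relative abundances of all peptides
#' mapping to one protein. Protein-level TPP conventionally fits one curve
#' per protein; phospho-TPP instead fits each peptide individually, so this
#' aggregation is an optional mode, not a default.
#'
#' @param peptide_profiles numeric matrix, one row per peptide, one column
#'   per temperature channel (normalized scale)
#' @return numeric vector: the per-channel median profile
#' @export
aggregate_to_protein <- function(peptide_profiles) {
  m <- as.matrix(peptide_profiles)
  if (nrow(m) < 1L) stop("at least one peptide profile required")
  apply(m, 2L, stats::median, na.rm = TRUE)
}

#' Fit melting curves for every profile of a TPP table
#'
#' Normalizes each row to its lowest-temperature channel, optionally
#' aggregates peptides to proteins (channel-wise median on the normalized
#' scale) before fitting, and fits the melting sigmoid per feature and
#' experiment.
#'
#' @param tab a `tpp_table` (see [read_tpp_table()] / [simulate_tpp_experiment()])
#' @param level `"asis"` fits each row as stored (the peptide-level mode);
#'   `"protein"` aggregates rows sharing a protein id before fitting.
#'   Protein ids are derived from `feature_id` by stripping a
#'   `_p[STY]<pos>`-style phosphosite suffix and any trailing `_pep<k>`
#'   peptide index.
#' @param min_channels,guard passed to [fit_melting_curve()]
#' @return data.frame with one row per fitted profile: the experiment key
#'   columns plus `p`, `a`, `b`, `tm`, `r2`, `min_slope`, `rss`,
#'   `converged`, `status` and `plateau` (alias of `p`, kept for QC
#'   readability). Rows whose reference channel was unusable appear with
#'   status `"unusable"`.
#' @export
fit_melting_table <- function(tab, level = c("asis", "protein"),
                              min_channels = 8L, guard = 5) {
  level <- match.arg(level)
  temps <- tpp_temperatures(tab)
  ic <- tpp_intensity_cols(tab)
  meta <- tab[, c("feature_id", "cell_line", "treatment", "layout",
                  "replicate"), drop = FALSE]
  ymat <- t(apply(as.matrix(tab[, ic, drop = FALSE]), 1L, function(r) {
    normalize_profile(r)$y
  }))

  if (level == "protein") {
    pid <- strip_feature_suffix(meta$feature_id)
    key <- paste(pid, meta$cell_line, meta$treatment, meta$layout,
                 meta$replicate, sep = "\r")
    idx <- split(seq_len(nrow(tab)), key)
    meta_list <- lapply(idx, function(i) {
      m <- meta[i[1L], , drop = FALSE]
      m$feature_id <- pid[i[1L]]
      m
    })
    ymat <- do.call(rbind, lapply(idx, function(i) {
      aggregate_to_protein(ymat[i, , drop = FALSE])
    }))
    meta <- do.call(rbind, meta_list)
    ord <- order(meta$feature_id, meta$cell_line, meta$treatment,
                 meta$layout, meta$replicate)
    meta <- meta[ord, , drop = FALSE]
    ymat <- ymat[ord, , drop = FALSE]
  }

  fits <- lapply(seq_len(nrow(meta)), function(i) {
    fit_melting_curve(temps, ymat[i, ], min_channels = min_channels,
                      guard = guard)
  })
  res <- cbind(
    meta,
    data.frame(
      p = vapply(fits, `[[`, 0, "p"),
      a = vapply(fits, `[[`, 0, "a"),
      b = vapply(fits, `[[`, 0, "b"),
      tm = vapply(fits, `[[`, 0, "tm"),
      r2 = vapply(fits, `[[`, 0, "r2"),
      min_slope = vapply(fits, `[[`, 0, "min_slope"),
      rss = vapply(fits, `[[`, 0, "rss"),
      converged = vapply(fits, `[[`, TRUE, "converged"),
      status = vapply(fits, `[[`, "", "status"),
      stringsAsFactors = FALSE))
  res$plateau <- res$p
  rownames(res) <- NULL
  res
}

#' Strip phosphosite / peptide-index suffixes from a feature id
#'
#' `PROT1_pS123` -> `PROT1`; `PROT1_pep2` -> `PROT1`; plain protein ids pass
#' through unchanged.
#'
#' @param ids character vector of feature ids
#' @return character vector of protein ids
#' @export
strip_feature_suffix <- function(ids) {
  out <- sub("_p[STY][0-9]+$", "", ids)
  sub("_pep[0-9]+$", "", out)
}

#' Cross-experiment median normalization of TPP profiles
#'
#' Reporter-level systematic differences between the experiments of one TPP
#' run (e.g. labeling efficiency per channel) are corrected on the
#' normalized scale. A jointly observed feature subset (complete, usable
#' profiles present in every experiment) defines a per-experiment median
#' profile; the per-temperature correction factor for an experiment is the
#' across-experiment median of those medians divided by the experiment's own
#' median, so identical experiments receive exactly identity factors. A
#' sigmoid fitted to the across-experiment median profile is returned as a
#' QC summary of the normalization target.
#'
#' @param tab a `tpp_table` covering one TPP run (several experiments)
#' @param min_features minimum size of the jointly observed subset (default
#'   50); below it, normalization is skipped with a warning and identity
#'   factors are reported
#' @return list with `table` (corrected `tpp_table`), `factors` (matrix
#'   experiments x temperatures), `n_subset` (size of the joint subset),
#'   `applied` (logical) and `target_fit` (the `melting_fit` of the median
#'   profile, or NULL when skipped)
#' @export
median_normalize <- function(tab, min_features = 50L) {
  temps <- tpp_temperatures(tab)
  ic <- tpp_intensity_cols(tab)
  expkey <- paste(tab$cell_line, tab$treatment, tab$layout, tab$replicate,
                  sep = "|")
  exps <- sort(unique(expkey))
  raw <- as.matrix(tab[, ic, drop = FALSE])
  norm <- t(apply(raw, 1L, function(r) normalize_profile(r)$y))

  complete <- stats::complete.cases(norm)
  feat_by_exp <- tapply(tab$feature_id[complete], expkey[complete], unique)
  joint <- Reduce(intersect, feat_by_exp[exps])
  n_subset <- length(joint)

  factors <- matrix(1, nrow = length(exps), ncol = length(temps),
                    dimnames = list(exps, colnames(tab)[ic]))
  if (n_subset < min_features) {
    warning(sprintf(
      "median normalization skipped: joint feature subset has %d < %d features",
      n_subset, min_features))
    return(list(table = tab, factors = factors, n_subset = n_subset,
                applied = FALSE, target_fit = NULL))
  }

  sel <- complete & tab$feature_id %in% joint
  med <- matrix(NA_real_, nrow = length(exps), ncol = length(temps),
                dimnames = dimnames(factors))
  for (e in exps) {
    med[e, ] <- apply(norm[sel & expkey == e, , drop = FALSE], 2L,
                      stats::median)
  }
  target <- apply(med, 2L, stats::median)
  target_fit <- fit_melting_curve(temps, target)
  for (e in exps) factors[e, ] <- target / med[e, ]

  corrected <- raw
  for (e in exps) {
    rows <- expkey == e
    corrected[rows, ] <- sweep(raw[rows, , drop = FALSE], 2L, factors[e, ], `*`)
  }
  tab[, ic] <- corrected
  list(table = tab, factors = factors, n_subset = n_subset, applied = TRUE,
       target_fit = target_fit)
}
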