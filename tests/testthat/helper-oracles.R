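# Independent oracles used against the package implementations. These stay
# deliberately naive: grid refinement instead of gradient descent, direct
# textbook formulas, exhaustive enumeration on small universes.

DEFAULT_TEMPS <- c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67)

# Sigmoid profile from (p, Tm, b), solving a = Tm * (b - ln(0.5/(0.5-p)))
# so the planted melting point is exact by construction.
make_profile <- function(temps, p, tm, b) {
  a <- tm * (b - log(0.5 / (0.5 - p)))
  list(y = melt_sigmoid(temps, p, a, b), a = a)
}

# Dense grid-refinement least-squares oracle over (p, Tm, b). Each round
# evaluates a 21^3 lattice (vectorized) and shrinks the box around the best
# point slowly enough not to lose the global basin.
oracle_grid_sse <- function(temps, y, rounds = 10L) {
  lo <- c(p = 0, tm = 30, b = 2)
  hi <- c(p = 0.4, tm = 75, b = 60)
  best <- NULL
  npts <- 21L
  for (r in seq_len(rounds)) {
    g <- expand.grid(p = seq(lo["p"], hi["p"], length.out = npts),
                     tm = seq(lo["tm"], hi["tm"], length.out = npts),
                     b = seq(lo["b"], hi["b"], length.out = npts))
    a <- g$tm * (g$b - log(0.5 / (0.5 - pmin(g$p, 0.499))))
    sse <- rep(0, nrow(g))
    for (j in seq_along(temps)) {
      pred <- (1 - g$p) / (1 + exp(-(a / temps[j] - g$b))) + g$p
      sse <- sse + (y[j] - pred)^2
    }
    i <- which.min(sse)
    if (is.null(best) || sse[i] < best$sse) {
      best <- list(sse = sse[i], p = g$p[i], tm = g$tm[i], b = g$b[i])
    }
    span <- (hi - lo) / (npts - 1) * 2.5   # keep +/- 2.5 lattice steps
    lo <- pmax(c(best$p, best$tm, best$b) - span, c(0, 30, 2))
    hi <- pmin(c(best$p, best$tm, best$b) + span, c(0.4, 75, 60))
    names(lo) <- names(hi) <- c("p", "tm", "b")
  }
  best
}

# Student's equal-variance two-sample t-test from the textbook formulas.
oracle_ttest <- function(xa, xb) {
  na <- length(xa); nb <- length(xb)
  sp2 <- ((na - 1) * var(xa) + (nb - 1) * var(xb)) / (na + nb - 2)
  t <- (mean(xa) - mean(xb)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# Exhaustive hypergeometric upper tail: enumerate every possible query draw
# of size n from a universe of size N with K term members, and count draws
# with overlap >= k. Feasible for N <= 20.
oracle_hyper_upper <- function(k, K, N, n) {
  draws <- combn(N, n)
  in_term <- seq_len(N) <= K   # wlog the first K elements are the term
  mean(colSums(matrix(in_term[draws], nrow = n)) >= k)
}

# Brute-force set algebra by element-wise membership loops.
oracle_setdiff <- function(a, b) {
  out <- character(0)
  for (x in a) {
    found <- FALSE
    for (y in b) if (identical(x, y)) found <- TRUE
    if (!found) out <- c(out, x)
  }
  sort(unique(out))
}
oracle_intersect_all <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  out <- character(0)
  for (x in universe) {
    in_all <- TRUE
    for (s in sets) {
      found <- FALSE
      for (y in s) if (identical(x, y)) found <- TRUE
      if (!found) in_all <- FALSE
    }
    if (in_all) out <- c(out, x)
  }
  out
}

# Small TPP fixture table built in code.
make_tpp_fixture <- function(n = 3L, temps = DEFAULT_TEMPS,
                             level = "protein") {
  rows <- lapply(seq_len(n), function(i) {
    prof <- make_profile(temps, p = 0.1, tm = 48 + i, b = 30)
    df <- data.frame(feature_id = sprintf("P%02d", i), feature_level = level,
                     cell_line = "lineA", treatment = "vehicle",
                     layout = "lysate", replicate = 1L,
                     stringsAsFactors = FALSE)
    df[paste0("T", temps)] <- as.list(prof$y * 1e6)
    df
  })
  tpp_table(do.call(rbind, rows))
}
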