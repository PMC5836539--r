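# Zero interaction potency (ZIP) scoring of drug-combination dose-response
# matrices. Monotherapy rows/columns are fit with four-parameter logistic
# curves; for each combination dose the response is re-fit conditionally
# along each drug with the baseline anchored at the other drug's monotherapy
# effect (the potency-shift view), and delta is the fitted combination
# effect minus the multiplicative zero-interaction expectation. Positive
# delta = synergy, negative = antagonism.

#' Convert a viability matrix to the inhibition scale
#'
#' `inhibition = 1 - viability`, clipped to `[0, 1]`. Overgrowth wells
#' (viability above 1) clip to 0 inhibition and are flagged rather than
#' silently altered.
#'
#' @param dm a `dose_matrix` of viability fractions relative to vehicle
#' @return list with `inhibition` (matrix), `clipped` (logical matrix of
#'   wells that were clipped) and the dose vectors
#' @export
to_inhibition <- function(dm) {
  stopifnot(inherits(dm, "dose_matrix"))
  if (is.na(dm$response[1L, 1L])) stop("vehicle (0, 0) well is missing")
  y <- 1 - dm$response
  clipped <- y < 0 | y > 1
  y <- pmin(pmax(y, 0), 1)
  list(inhibition = y, clipped = clipped, doses1 = dm$doses1,
       doses2 = dm$doses2)
}

#' Zero-interaction expected combination inhibition
#'
#' The multiplicative-survival null: `y1 + y2 - y1 * y2`. Symmetric,
#' bounded in `[0, 1]`, monotone in each argument, with 0 as identity and 1
#' as absorbing element.
#'
#' @param y1,y2 inhibition fractions in `[0, 1]` (recycled)
#' @return expected combination inhibition
#' @export
zip_expected <- function(y1, y2) {
  if (any(y1 < 0 | y1 > 1 | y2 < 0 | y2 > 1, na.rm = TRUE)) {
    stop("inhibition fractions must lie in [0, 1]")
  }
  y1 + y2 - y1 * y2
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `y(x) = y_min + (y_max - y_min) / (1 + (m/x)^lambda)` on the inhibition
#' scale, with `y(0) = y_min`. Constraints: `m > 0`, `lambda` in
#' `[0.1, 10]`, `0 <= y_min <= y_max <= 1`. Doses are handled on the log
#' scale internally; the zero dose anchors the baseline and never enters a
#' logarithm. Either asymptote can be fixed (used by the conditional ZIP
#' fits, which anchor the baseline at the other drug's monotherapy effect).
#'
#' @param doses ascending doses including 0
#' @param responses inhibition fractions, same length
#' @param y_min_fixed optional fixed baseline
#' @param y_max_fixed optional fixed top asymptote
#' @return list of class `logistic_fit`: `m` (EC50), `lambda` (Hill slope),
#'   `y_min`, `y_max`, `rss`, `converged`
#' @export
fit_logistic <- function(doses, responses, y_min_fixed = NULL,
                         y_max_fixed = NULL) {
  stopifnot(length(doses) == length(responses))
  ok <- !is.na(responses)
  doses <- doses[ok]; responses <- responses[ok]
  if (length(doses) < 4L || !any(doses == 0)) {
    stop("at least four dose points including 0 are required")
  }
  out <- list(m = NA_real_, lambda = NA_real_, y_min = NA_real_,
              y_max = NA_real_, rss = NA_real_, converged = FALSE)
  class(out) <- "logistic_fit"

  pos <- doses > 0
  ymin0 <- if (is.null(y_min_fixed)) max(min(responses), 0) else y_min_fixed
  ymax0 <- if (is.null(y_max_fixed)) min(max(responses), 1) else y_max_fixed
  ymax0 <- max(ymax0, ymin0 + 1e-6)
  # EC50 seed: dose where the response crosses halfway between asymptotes
  half <- (ymin0 + ymax0) / 2
  above <- which(responses >= half & pos)
  m0 <- if (length(above)) doses[above[1L]] else stats::median(doses[pos])
  m0 <- max(m0, min(doses[pos]))

  pred <- function(par) {
    m <- exp(par[["logm"]]); lam <- par[["lambda"]]
    ymin <- if (is.null(y_min_fixed)) par[["ymin"]] else y_min_fixed
    ymax <- if (is.null(y_max_fixed)) par[["ymax"]] else y_max_fixed
    ifelse(doses == 0, ymin,
           ymin + (ymax - ymin) / (1 + (m / doses)^lam))
  }
  resid_fun <- function(par) responses - pred(par)

  par0 <- c(logm = log(m0), lambda = 1.5)
  lower <- c(logm = log(min(doses[pos]) / 100), lambda = 0.1)
  upper <- c(logm = log(max(doses[pos]) * 100), lambda = 10)
  if (is.null(y_min_fixed)) {
    par0 <- c(par0, ymin = ymin0); lower <- c(lower, ymin = 0)
    upper <- c(upper, ymin = 1)
  }
  if (is.null(y_max_fixed)) {
    par0 <- c(par0, ymax = ymax0); lower <- c(lower, ymax = 0)
    upper <- c(upper, ymax = 1)
  }

  best <- NULL
  for (lam0 in c(1.5, 0.5, 4)) {
    p0 <- par0; p0[["lambda"]] <- lam0
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(par = fit$par, rss = rss)
    if (best$rss < 1e-12) break
  }
  if (is.null(best)) return(out)
  par <- best$par
  out$m <- exp(par[["logm"]])
  out$lambda <- par[["lambda"]]
  out$y_min <- if (is.null(y_min_fixed)) par[["ymin"]] else y_min_fixed
  out$y_max <- if (is.null(y_max_fixed)) par[["ymax"]] else y_max_fixed
  if (out$y_max < out$y_min) {   # enforce ordering of free asymptotes
    tmp <- out$y_min; out$y_min <- out$y_max; out$y_max <- tmp
  }
  out$rss <- best$rss
  out$converged <- TRUE
  out
}

#' Predict from a logistic fit
#'
#' @param object a `logistic_fit`
#' @param doses doses at which to evaluate (0 allowed)
#' @param ... unused
#' @return predicted inhibition fractions
#' @export
predict.logistic_fit <- function(object, doses, ...) {
  ifelse(doses == 0, object$y_min,
         object$y_min + (object$y_max - object$y_min) /
           (1 + (object$m / doses)^object$lambda))
}

#' ZIP delta surface for one dose-response matrix
#'
#' Fits the monotherapy rows, then for each combination dose level re-fits
#' the response conditionally along each drug with the baseline anchored at
#' the other drug's fitted monotherapy effect. The fitted combination
#' effect at a well is the average of the two conditional predictions;
#' `delta = fitted - zip_expected(y1_hat, y2_hat)`. If one conditional fit
#' fails, the surviving direction is used alone and the wells are flagged.
#'
#' @param dm a `dose_matrix` (viability scale)
#' @return object of class `synergy_map`: list with `delta` (matrix over
#'   combination doses), `summary_delta` (mean over combination wells),
#'   `fit1`, `fit2` (monotherapy `logistic_fit`s), `fitted`, `expected`
#'   (matrices), `flagged` (logical matrix of wells with a failed
#'   conditional fit), `doses1`, `doses2`
#' @export
zip_delta <- function(dm) {
  inh <- to_inhibition(dm)
  d1 <- inh$doses1; d2 <- inh$doses2
  y <- inh$inhibition
  if (length(d1) < 4L || length(d2) < 4L) {
    stop("at least four doses per drug are required")
  }
  fit1 <- fit_logistic(d1, y[, 1L], y_min_fixed = 0)
  fit2 <- fit_logistic(d2, y[1L, ], y_min_fixed = 0)
  y1_hat <- predict(fit1, d1)
  y2_hat <- predict(fit2, d2)

  nc1 <- length(d1) - 1L; nc2 <- length(d2) - 1L
  fitted_along2 <- matrix(NA_real_, nc1, nc2)   # fits along drug 2 rows
  fitted_along1 <- matrix(NA_real_, nc1, nc2)   # fits along drug 1 columns
  for (i in seq_len(nc1)) {      # fixed drug-1 dose d1[i + 1]
    anchor <- y1_hat[i + 1L]
    row <- c(anchor, y[i + 1L, -1L])   # baseline well + combination wells
    f <- tryCatch(fit_logistic(d2, row, y_min_fixed = anchor),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      fitted_along2[i, ] <- predict(f, d2[-1L])
    }
  }
  for (j in seq_len(nc2)) {      # fixed drug-2 dose d2[j + 1]
    anchor <- y2_hat[j + 1L]
    col <- c(anchor, y[-1L, j + 1L])
    f <- tryCatch(fit_logistic(d1, col, y_min_fixed = anchor),
                  error = function(e) NULL)
    if (!is.null(f) && f$converged) {
      fitted_along1[, j] <- predict(f, d1[-1L])
    }
  }
  flagged <- is.na(fitted_along1) | is.na(fitted_along2)
  fitted <- matrix(rowMeans(cbind(as.vector(fitted_along1),
                                  as.vector(fitted_along2)), na.rm = TRUE),
                   nc1, nc2)
  expected <- outer(y1_hat[-1L], y2_hat[-1L], zip_expected)
  delta <- fitted - expected
  structure(list(delta = delta, summary_delta = mean(delta, na.rm = TRUE),
                 fit1 = fit1, fit2 = fit2, fitted = fitted,
                 expected = expected, flagged = flagged,
                 clipped = inh$clipped, doses1 = d1, doses2 = d2),
            class = "synergy_map")
}

#' @export
print.synergy_map <- function(x, ...) {
  cat(sprintf("synergy_map: %d x %d combination wells, summary delta %+.4f\n",
              nrow(x$delta), ncol(x$delta), x$summary_delta))
  invisible(x)
}

#' Summarize ZIP delta surfaces across replicates
#'
#' @param maps list of `synergy_map`s on identical dose grids
#' @return list with `mean_delta` and `sd_delta` (matrices),
#'   `summary_delta` (mean of replicate summaries) and `summary_sd`
#' @export
replicate_summary <- function(maps) {
  if (length(maps) < 2L) stop("at least two replicate maps are required")
  g1 <- maps[[1L]]$doses1; g2 <- maps[[1L]]$doses2
  for (m in maps[-1L]) {
    if (!isTRUE(all.equal(m$doses1, g1)) ||
        !isTRUE(all.equal(m$doses2, g2))) {
      stop("replicate maps are on different dose grids")
    }
  }
  arr <- simplify2array(lapply(maps, `[[`, "delta"))
  summaries <- vapply(maps, `[[`, 0, "summary_delta")
  list(mean_delta = apply(arr, c(1L, 2L), mean),
       sd_delta = apply(arr, c(1L, 2L), stats::sd),
       summary_delta = mean(summaries),
       summary_sd = stats::sd(summaries))
}
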