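# Seeded generator for every input the pipeline consumes, with recorded
# ground truth. The geometry mirrors the study design being emulated: ten
# TMT temperature channels, two biological replicates for TPP, two cell
# lines (one drug-sensitive, one resistant) x {DMSO, BRAFi, Hsp90i, combo}
# x three replicates for expression, full dose-by-dose viability matrices in
# three replicates, and grouped two-gene expression panels.

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Named substreams: each stage draws from seed + fixed offset so stages are
# independently reproducible.
.substream <- function(seed, stage) {
  offsets <- c(tpp = 101L, expression = 211L, doses = 307L, coexpr = 401L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulation configuration
#'
#' One seeded configuration drives every synthetic input. All defaults are
#' the study conditions the generator emulates; they are validated, not
#' inferred.
#'
#' @param seed integer; fully determines all outputs
#' @param n_features number of simulated features
#' @param temperatures ten ascending channel temperatures in degC (default
#'   the conventional 37-67 degC TMT10 gradient)
#' @param n_replicates biological replicates for TPP (default 2)
#' @param cell_lines two cell-line names; the first is the drug-sensitive
#'   line, the second the resistant line
#' @param layouts TPP layouts to emulate (subset of `c("lysate", "intact")`)
#' @param shift_fraction proportion of features with a planted drug-induced
#'   melting-point shift
#' @param shift_magnitude planted delta-Tm in degC (drug minus vehicle)
#' @param line_shift_fraction,line_shift_magnitude proportion/magnitude of
#'   features with a planted baseline Tm difference between the two cell
#'   lines (the cross-line comparison signal)
#' @param discordant_fraction proportion of features planted as
#'   discordant-sign decoys (shift `+magnitude` in replicate 1,
#'   `-magnitude` in replicate 2) to exercise the replicate-concordance rule
#' @param noise_sd relative (multiplicative log-normal) reporter-intensity
#'   noise
#' @param feature_level `"protein"`, `"peptide"` or `"phosphopeptide"`
#' @param de_fraction proportion of features regulated per (cell line,
#'   treatment vs DMSO) comparison in the expression study
#' @param de_effect planted fold change (>= 1; direction is assigned
#'   separately)
#' @param expr_noise_sd per-sample noise on log2 intensities
#' @param reg_counts optional named vector `c(shared=, resistant_only=,
#'   sensitive_only=)` of planted feature counts per treatment and
#'   direction; overrides the `de_fraction` split when given
#' @param n_core number of resistant-only upregulated features shared across
#'   all three treatments (the three-way-intersection structure)
#' @param loc_below_fraction fraction of phosphopeptide rows planted with
#'   localization probability below 0.75
#' @param doses1,doses2 dose vectors (ascending, starting at 0) for the
#'   synergy matrices
#' @param ec50_1,hill_1,ec50_2,hill_2 monotherapy four-parameter-logistic
#'   parameters (EC50 in dose units; Hill slope unitless)
#' @param planted_delta uniform synergy offset added to every combination
#'   well on the inhibition scale (positive = synergy)
#' @param viability_noise_sd additive Gaussian noise on viability fractions
#' @param n_dose_replicates replicate dose matrices
#' @param group_correlations named numeric vector of per-group target
#'   Pearson correlations for the co-expression panel
#' @param n_per_group samples per co-expression group
#' @param coexpr_genes names of the two panel genes
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_features = 1000L,
                       temperatures = c(37, 41, 44, 47, 50, 53, 56, 59, 63, 67),
                       n_replicates = 2L,
                       cell_lines = c("SK-Mel-24", "SK-Mel-28"),
                       layouts = "lysate",
                       shift_fraction = 0.05,
                       shift_magnitude = 4,
                       line_shift_fraction = 0.05,
                       line_shift_magnitude = 3,
                       discordant_fraction = 0,
                       noise_sd = 0.02,
                       feature_level = c("protein", "peptide",
                                         "phosphopeptide"),
                       de_fraction = 0.1,
                       de_effect = 2,
                       expr_noise_sd = 0.3,
                       reg_counts = NULL,
                       n_core = 3L,
                       loc_below_fraction = 0.2,
                       doses1 = c(0, 2^seq(-4, 2)),
                       doses2 = c(0, 2^seq(-6, 0)),
                       ec50_1 = 3, hill_1 = 1.5,
                       ec50_2 = 0.8, hill_2 = 1.2,
                       planted_delta = 0,
                       viability_noise_sd = 0.02,
                       n_dose_replicates = 3L,
                       group_correlations = c(melanoma = 0.8, glioma = 0.6,
                                              lung = 0.0),
                       n_per_group = 60L,
                       coexpr_genes = c("MITF", "CDK2")) {
  feature_level <- match.arg(feature_level)
  cfg <- as.list(environment())
  fracs <- c(shift_fraction, line_shift_fraction, discordant_fraction,
             de_fraction, loc_below_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("all fractions must lie in [0, 1]")
  if (noise_sd < 0 || expr_noise_sd < 0 || viability_noise_sd < 0) {
    stop("noise levels must be non-negative")
  }
  if (de_effect < 1) {
    stop("de_effect is a fold change >= 1; direction is assigned separately")
  }
  if (length(temperatures) != 10L || any(diff(temperatures) <= 0)) {
    stop("temperatures must be ten strictly ascending values")
  }
  if (length(cell_lines) != 2L) stop("exactly two cell lines are modeled")
  if (any(diff(doses1) <= 0) || any(diff(doses2) <= 0) ||
      doses1[1L] != 0 || doses2[1L] != 0) {
    stop("dose vectors must be ascending and start at 0")
  }
  if (any(abs(group_correlations) > 1)) {
    stop("group correlations must lie in [-1, 1]")
  }
  if (n_per_group < 3L) stop("co-expression groups need n >= 3")
  if (!is.null(reg_counts)) {
    need <- c("shared", "resistant_only", "sensitive_only")
    if (!all(need %in% names(reg_counts))) {
      stop("reg_counts needs names: ", paste(need, collapse = ", "))
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a TPP experiment with planted thermal shifts
#'
#' For every feature x cell line x layout x treatment x replicate, reporter
#' intensities are drawn around the melting sigmoid
#' `f(T) = (1 - p)/(1 + exp(-(a/T - b))) + p`, scaled by a feature-level
#' abundance, with multiplicative log-normal noise. True plateaus lie in
#' `[0, 0.3]` and true Tm in `[42, 60]` degC so curves stay inside the
#' gradient and pass QC. Shifted features move Tm by `shift_magnitude`
#' under drug in both replicates (holding plateau and slope); the resistant
#' line additionally carries baseline Tm offsets for the planted
#' line-shift set. Discordant decoys (if configured) flip the sign of the
#' shift in replicate 2.
#'
#' @param config a [sim_config()]
#' @return list with `table` (a `tpp_table`) and `truth` (data.frame of true
#'   parameters and planted-set membership per feature)
#' @export
simulate_tpp_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream(config$seed, "tpp"), {
    n <- config$n_features
    ids <- sprintf("PROT%05d", seq_len(n))
    if (config$feature_level == "phosphopeptide") {
      ids <- paste0(ids, "_pS", sample(10:999, n, replace = TRUE))
    }
    n_shift <- round(config$shift_fraction * n)
    if (config$shift_fraction > 0 && config$shift_magnitude > 0 &&
        n_shift < 1L) {
      warning("shift_fraction x n_features < 1; planted shifted set is empty")
    }
    n_disc <- round(config$discordant_fraction * n)
    n_line <- round(config$line_shift_fraction * n)
    idx_all <- sample(n)   # disjoint planted sets
    shifted <- idx_all[seq_len(n_shift)]
    discordant <- idx_all[seq_len(n_disc) + n_shift]
    line_shifted <- sample(n, n_line)   # may overlap drug-shift sets

    # plateaus below the 0.3 QC gate and slope parameters steep enough to
    # clear the -0.06 1/degC steepest-slope gate across the whole Tm range:
    # the planted biology is meant to survive curve QC
    p_true <- stats::runif(n, 0, 0.25)
    tm_true <- stats::runif(n, 42, 60)
    b_true <- stats::runif(n, 26, 40)
    abund <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 0.5)

    a_for <- function(tm, p, b) tm * (b - log(0.5 / (0.5 - p)))

    level <- if (config$feature_level == "protein") "protein" else "peptide"
    rows <- list()
    truth_tm <- list()
    for (cl_i in seq_along(config$cell_lines)) {
      cl <- config$cell_lines[cl_i]
      tm_base <- tm_true
      if (cl_i == 2L && length(line_shifted)) {
        tm_base[line_shifted] <- tm_base[line_shifted] +
          config$line_shift_magnitude
      }
      for (lay in config$layouts) {
        for (trt in c("vehicle", "drug")) {
          for (rep_i in seq_len(config$n_replicates)) {
            tm_cond <- tm_base
            if (trt == "drug") {
              tm_cond[shifted] <- tm_cond[shifted] + config$shift_magnitude
              sgn <- if (rep_i == 2L) -1 else 1
              tm_cond[discordant] <- tm_cond[discordant] +
                sgn * config$shift_magnitude
            }
            a_cond <- a_for(tm_cond, p_true, b_true)
            f <- vapply(config$temperatures, function(temp) {
              melt_sigmoid(temp, p_true, a_cond, b_true)
            }, numeric(n))
            noise <- matrix(
              exp(stats::rnorm(n * 10L, 0, config$noise_sd)), nrow = n)
            intens <- abund * f * noise
            df <- data.frame(feature_id = ids, feature_level = level,
                             cell_line = cl, treatment = trt, layout = lay,
                             replicate = rep_i, stringsAsFactors = FALSE)
            df[paste0("T", config$temperatures)] <- as.data.frame(intens)
            rows[[length(rows) + 1L]] <- df
            truth_tm[[length(truth_tm) + 1L]] <- data.frame(
              feature_id = ids, cell_line = cl, layout = lay,
              treatment = trt, replicate = rep_i, true_tm = tm_cond,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    tab <- tpp_table(do.call(rbind, rows))
    truth <- list(
      params = data.frame(feature_id = ids, p = p_true, b = b_true,
                          tm_vehicle = tm_true, abundance = abund,
                          shifted = seq_len(n) %in% shifted,
                          discordant = seq_len(n) %in% discordant,
                          line_shifted = seq_len(n) %in% line_shifted,
                          stringsAsFactors = FALSE),
      shifted_set = ids[shifted],
      discordant_set = ids[discordant],
      line_shifted_set = ids[line_shifted],
      per_condition_tm = do.call(rbind, truth_tm))
    list(table = tab, truth = truth)
  })
}

# Planted regulation bookkeeping for one treatment/direction: disjoint
# shared / resistant-only / sensitive-only sets drawn from the feature pool.
.draw_reg_sets <- function(pool, counts, core = integer(0)) {
  res_only <- core
  pool <- setdiff(pool, core)
  take <- function(k) {
    k <- min(k, length(pool))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  res_only <- c(res_only, take(max(counts[["resistant_only"]] -
                                     length(core), 0L)))
  list(shared = take(counts[["shared"]]),
       resistant_only = res_only,
       sensitive_only = take(counts[["sensitive_only"]]))
}

#' Simulate a label-free (phospho)proteome expression study
#'
#' Two cell lines (sensitive first, resistant second) x four treatments
#' (DMSO, BRAFi, Hsp90i, combo) x three replicates. Intensities are
#' log-normal; regulated features receive the configured fold change in the
#' treated samples of the affected line(s). The planted structure guarantees
#' a resistant-unique regulated stratum per treatment (the subtractive
#' analysis signal) and an `n_core`-feature resistant-only upregulated set
#' shared by all three treatments (the three-way intersection signal).
#' Phosphopeptide rows carry localization probabilities with a configured
#' fraction planted below the 0.75 confidence threshold.
#'
#' @param config a [sim_config()]
#' @return list with `table` (an `expression_table`) and `truth` (planted
#'   regulated sets per cell line, treatment and direction; core set;
#'   sub-threshold localization rows)
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream(config$seed, "expression"), {
    n <- config$n_features
    is_phos <- config$feature_level == "phosphopeptide"
    ids <- sprintf("PROT%05d", seq_len(n))
    if (is_phos) ids <- paste0(ids, "_pS", sample(10:999, n, replace = TRUE))

    treatments <- c("DMSO", "BRAFi", "Hsp90i", "combo")
    drug_trts <- setdiff(treatments, "DMSO")
    counts <- if (!is.null(config$reg_counts)) {
      round(config$reg_counts)
    } else {
      per_dir <- round(config$de_fraction * n / 2)
      c(shared = round(0.4 * per_dir),
        resistant_only = round(0.3 * per_dir),
        sensitive_only = round(0.3 * per_dir))
    }

    pool <- sample(n)
    core <- if (config$n_core > 0L) pool[seq_len(config$n_core)] else integer(0)
    pool <- setdiff(pool, core)

    reg <- list()   # reg[[treatment]][[direction]] = list of index sets
    for (trt in drug_trts) {
      for (dir in c("up", "down")) {
        sets <- .draw_reg_sets(pool, counts,
                               core = if (dir == "up") core else integer(0))
        used <- c(sets$shared, setdiff(sets$resistant_only, core),
                  sets$sensitive_only)
        pool <- setdiff(pool, used)
        reg[[trt]][[dir]] <- sets
      }
    }

    base_log2 <- stats::rnorm(n, mean = 20, sd = 1.5)
    line_offset <- stats::rnorm(n, 0, 0.1)
    lfc <- log2(config$de_effect)

    samples <- expand.grid(replicate = 1:3, treatment = treatments,
                           cell_line = config$cell_lines,
                           stringsAsFactors = FALSE)
    samples <- samples[, c("cell_line", "treatment", "replicate")]
    mat <- matrix(NA_real_, nrow = n, ncol = nrow(samples))
    sensitive <- config$cell_lines[1L]
    resistant <- config$cell_lines[2L]
    for (s in seq_len(nrow(samples))) {
      cl <- samples$cell_line[s]; trt <- samples$treatment[s]
      mu <- base_log2 + if (cl == resistant) line_offset else 0
      if (trt != "DMSO") {
        r <- reg[[trt]]
        up <- c(r$up$shared,
                if (cl == resistant) r$up$resistant_only else r$up$sensitive_only)
        dn <- c(r$down$shared,
                if (cl == resistant) r$down$resistant_only else r$down$sensitive_only)
        mu[up] <- mu[up] + lfc
        mu[dn] <- mu[dn] - lfc
      }
      mat[, s] <- 2^(mu + stats::rnorm(n, 0, config$expr_noise_sd))
    }

    loc <- rep(NA_real_, n)
    below <- integer(0)
    if (is_phos) {
      n_below <- round(config$loc_below_fraction * n)
      below <- sample(n, n_below)
      loc <- stats::runif(n, 0.75, 1)
      loc[below] <- stats::runif(n_below, 0.3, 0.7499)
    }
    features <- data.frame(
      feature_id = ids,
      feature_level = if (is_phos) "phosphopeptide" else "protein",
      localization_probability = loc, stringsAsFactors = FALSE)
    tab <- expression_table(features, mat, samples)

    reg_row <- function(cl, trt, dir, idx) {
      if (!length(idx)) return(NULL)
      data.frame(cell_line = cl, treatment = trt, direction = dir,
                 feature_id = ids[sort(idx)], stringsAsFactors = FALSE)
    }
    reg_truth <- do.call(rbind, unlist(lapply(drug_trts, function(trt) {
      lapply(c("up", "down"), function(dir) {
        s <- reg[[trt]][[dir]]
        rbind(reg_row(sensitive, trt, dir, c(s$shared, s$sensitive_only)),
              reg_row(resistant, trt, dir, c(s$shared, s$resistant_only)))
      })
    }), recursive = FALSE))
    if (is.null(reg_truth)) {
      reg_truth <- data.frame(cell_line = character(0),
                              treatment = character(0),
                              direction = character(0),
                              feature_id = character(0),
                              stringsAsFactors = FALSE)
    }
    truth <- list(
      regulated = reg_truth,
      core_up_resistant = ids[sort(core)],
      below_localization = ids[sort(below)],
      resistant_unique = lapply(stats::setNames(drug_trts, drug_trts),
        function(trt) {
          lapply(stats::setNames(c("up", "down"), c("up", "down")),
            function(dir) ids[sort(reg[[trt]][[dir]]$resistant_only)])
        }))
    list(table = tab, truth = truth)
  })
}

#' Simulate replicate dose-response matrices with a planted synergy offset
#'
#' Monotherapy inhibition follows four-parameter logistic curves with the
#' configured EC50 and Hill slope (full efficacy, zero baseline);
#' combination wells equal the zero-interaction (Bliss-multiplicative)
#' expectation `y1 + y2 - y1*y2` plus `planted_delta`, converted to
#' viability and perturbed with additive Gaussian noise.
#'
#' @param config a [sim_config()]
#' @return list with `matrices` (list of `dose_matrix`, one per replicate)
#'   and `truth` (monotherapy parameters, planted delta, true inhibition
#'   surface)
#' @export
simulate_dose_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream(config$seed, "doses"), {
    d1 <- config$doses1; d2 <- config$doses2
    y1 <- ifelse(d1 == 0, 0, 1 / (1 + (config$ec50_1 / d1)^config$hill_1))
    y2 <- ifelse(d2 == 0, 0, 1 / (1 + (config$ec50_2 / d2)^config$hill_2))
    inhib <- outer(y1, y2, function(a, b) a + b - a * b)
    combo <- outer(d1 > 0, d2 > 0, `&`)
    inhib[combo] <- inhib[combo] + config$planted_delta
    inhib <- pmin(pmax(inhib, 0), 1)
    mats <- lapply(seq_len(config$n_dose_replicates), function(r) {
      viab <- 1 - inhib +
        matrix(stats::rnorm(length(inhib), 0, config$viability_noise_sd),
               nrow = nrow(inhib))
      viab[1L, 1L] <- 1   # vehicle well defines the scale
      dose_matrix(d1, d2, pmax(viab, 0), replicate_id = r)
    })
    list(matrices = mats,
         truth = list(ec50 = c(config$ec50_1, config$ec50_2),
                      hill = c(config$hill_1, config$hill_2),
                      planted_delta = config$planted_delta,
                      inhibition = inhib))
  })
}

#' Simulate a grouped two-gene co-expression panel
#'
#' Per group, bivariate log2-scale Gaussian samples with the target Pearson
#' correlation (exact collinear construction at |r| = 1).
#'
#' @param config a [sim_config()]
#' @return list with `panel` (data.frame: `sample_id`, `group`, one column
#'   per gene, log2 expression) and `truth` (the target correlations)
#' @export
simulate_coexpression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(.substream(config$seed, "coexpr"), {
    rs <- config$group_correlations
    panels <- lapply(names(rs), function(g) {
      r <- rs[[g]]
      nx <- config$n_per_group
      x <- stats::rnorm(nx, 6, 1.5)
      z <- stats::rnorm(nx)
      y <- 7 + 1.2 * (r * scale(x)[, 1L] + sqrt(1 - r^2) * z)
      df <- data.frame(
        sample_id = sprintf("%s_%03d", g, seq_len(nx)),
        group = g, stringsAsFactors = FALSE)
      df[[config$coexpr_genes[1L]]] <- x
      df[[config$coexpr_genes[2L]]] <- y
      df
    })
    list(panel = do.call(rbind, panels),
         truth = list(group_correlations = rs))
  })
}
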