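# File formats used across the pipeline. All quant tables are UTF-8,
# tab-delimited with a header; dose matrices are CSV. Missing intensities are
# empty cells (absent), never zero: zero is a valid fully-denatured TPP
# measurement. Floats are serialized with %.10g so write -> read -> write is
# byte-stable. The shipped column schema is in
# inst/extdata/column_schema.tsv.

.TPP_META_COLS <- c("feature_id", "feature_level", "cell_line", "treatment",
                    "layout", "replicate")
.TPP_LEVELS <- c("protein", "peptide")
.TPP_TREATMENTS <- c("vehicle", "drug")
.TPP_LAYOUTS <- c("lysate", "intact")
.EXPR_TREATMENTS <- c("DMSO", "BRAFi", "Hsp90i", "combo")

.fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.10g", x))
  out
}

# Canonical tab/comma-delimited writer: fixed float formatting, NA as empty,
# no quoting, LF line endings. Deterministic given identical input.
.write_delim_canonical <- function(df, path, sep = "\t") {
  df2 <- df
  for (j in seq_along(df2)) {
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]])) {
      df2[[j]] <- .fmt_num(df2[[j]])
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  lines <- c(paste(colnames(df2), collapse = sep),
             do.call(paste, c(lapply(df2, function(col) {
               col <- as.character(col)
               col[is.na(col)] <- ""
               col
             }), sep = sep)))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Temperature channel columns of a TPP table
#'
#' @param tab a `tpp_table`
#' @return integer column indices of the ten intensity channels
#' @export
tpp_intensity_cols <- function(tab) {
  which(grepl("^T[0-9]+(\\.[0-9]+)?$", colnames(tab)))
}

#' Temperatures of a TPP table's channels
#'
#' @param tab a `tpp_table`
#' @return numeric vector of channel temperatures in degC
#' @export
tpp_temperatures <- function(tab) {
  as.numeric(sub("^T", "", colnames(tab)[tpp_intensity_cols(tab)]))
}

#' Construct and validate a TPP reporter-intensity table
#'
#' One row per (feature, cell line, treatment, layout, replicate) with ten
#' reporter-intensity channels named `T<temperature>`. Structural problems
#' (wrong channel count, non-monotone temperatures) are hard errors; row-level
#' schema violations (unknown enum value, negative intensity) are recorded in
#' the `invalid_rows` attribute and reported, never silently dropped.
#'
#' @param df data.frame with the metadata columns `feature_id`,
#'   `feature_level`, `cell_line`, `treatment`, `layout`, `replicate` and ten
#'   `T<temp>` intensity columns
#' @return `tpp_table` (a validated data.frame)
#' @export
tpp_table <- function(df) {
  missing_meta <- setdiff(.TPP_META_COLS, colnames(df))
  if (length(missing_meta)) {
    stop("missing required column(s): ", paste(missing_meta, collapse = ", "))
  }
  ic <- tpp_intensity_cols(df)
  if (length(ic) != 10L) {
    found <- colnames(df)[ic]
    stop(sprintf(
      "expected 10 temperature channel columns (T<temp>), found %d [%s]",
      length(ic), paste(found, collapse = ", ")))
  }
  temps <- as.numeric(sub("^T", "", colnames(df)[ic]))
  if (any(diff(temps) <= 0)) {
    stop("temperature channels must be strictly increasing; got: ",
         paste(temps, collapse = ", "))
  }
  for (j in ic) df[[j]] <- as.numeric(df[[j]])
  df$replicate <- as.integer(df$replicate)

  bad <- character(0)
  reasons <- list(
    feature_level = !df$feature_level %in% .TPP_LEVELS,
    treatment = !df$treatment %in% .TPP_TREATMENTS,
    layout = !df$layout %in% .TPP_LAYOUTS,
    replicate = is.na(df$replicate) | df$replicate < 1L,
    intensity = apply(df[, ic, drop = FALSE], 1L,
                      function(r) any(!is.na(r) & r < 0))
  )
  invalid <- data.frame(row = integer(0), reason = character(0),
                        stringsAsFactors = FALSE)
  for (nm in names(reasons)) {
    w <- which(reasons[[nm]])
    if (length(w)) {
      invalid <- rbind(invalid, data.frame(row = w, reason = nm,
                                           stringsAsFactors = FALSE))
    }
  }
  if (nrow(invalid)) {
    warning(sprintf("%d row(s) violate the TPP schema (kept, flagged): %s",
                    length(unique(invalid$row)),
                    paste(unique(invalid$reason), collapse = ", ")))
  }
  attr(df, "invalid_rows") <- invalid
  class(df) <- c("tpp_table", "data.frame")
  df
}

#' Read a TPP reporter-intensity table
#'
#' @param path tab-delimited file with a declared header (see [tpp_table()]
#'   for the schema)
#' @return validated `tpp_table`
#' @export
read_tpp_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  tpp_table(df)
}

#' Write a TPP table canonically
#'
#' Fixed float formatting and empty-cell NA encoding make the write -> read
#' round trip the identity byte-for-byte.
#'
#' @param tab a `tpp_table`
#' @param path output path
#' @return the path, invisibly
#' @export
write_tpp_table <- function(tab, path) {
  .write_delim_canonical(as.data.frame(tab), path, sep = "\t")
}

#' Construct a label-free expression table
#'
#' Container for proteome or phosphoproteome intensity matrices:
#' features x samples, with samples keyed by (cell line, treatment,
#' replicate). Phosphopeptide rows carry a localization probability
#' (confidence the phosphosite is on the stated residue); protein rows must
#' not.
#'
#' @param features data.frame with `feature_id`, `feature_level`
#'   (`"protein"` or `"phosphopeptide"`) and `localization_probability`
#'   (in `[0,1]` for phosphopeptides, `NA` for proteins)
#' @param intensities numeric matrix, rows matching `features`, columns
#'   matching `samples`
#' @param samples data.frame with `cell_line`, `treatment` (one of DMSO,
#'   BRAFi, Hsp90i, combo) and `replicate`
#' @return object of class `expression_table`
#' @export
expression_table <- function(features, intensities, samples) {
  stopifnot(nrow(features) == nrow(intensities),
            nrow(samples) == ncol(intensities))
  if (!all(samples$treatment %in% .EXPR_TREATMENTS)) {
    stop("unknown treatment(s): ",
         paste(setdiff(samples$treatment, .EXPR_TREATMENTS), collapse = ", "))
  }
  grp <- table(paste(samples$cell_line, samples$treatment))
  if (any(grp < 2L)) {
    stop("each (cell_line, treatment) group needs >= 2 samples; offending: ",
         paste(names(grp)[grp < 2L], collapse = ", "))
  }
  is_phos <- features$feature_level == "phosphopeptide"
  has_lp <- !is.na(features$localization_probability)
  if (any(is_phos != has_lp)) {
    stop("localization_probability must be present iff feature_level is ",
         "phosphopeptide")
  }
  samples$sample_id <- paste(samples$cell_line, samples$treatment,
                             paste0("R", samples$replicate), sep = "|")
  colnames(intensities) <- samples$sample_id
  rownames(intensities) <- features$feature_id
  structure(list(features = features, intensities = intensities,
                 samples = samples),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d features x %d samples (%s)\n",
              nrow(x$features), nrow(x$samples),
              paste(unique(x$features$feature_level), collapse = "+")))
  invisible(x)
}

#' Write an expression table canonically
#'
#' Tab-delimited: `feature_id`, `feature_level`, `localization_probability`,
#' then one column per sample named `<cell_line>|<treatment>|R<replicate>`.
#'
#' @param x an `expression_table`
#' @param path output path
#' @return the path, invisibly
#' @export
write_expression_table <- function(x, path) {
  df <- cbind(x$features[, c("feature_id", "feature_level",
                             "localization_probability")],
              as.data.frame(x$intensities, check.names = FALSE))
  .write_delim_canonical(df, path, sep = "\t")
}

#' Read an expression table
#'
#' @param path tab-delimited file as produced by [write_expression_table()]
#' @return `expression_table`
#' @export
read_expression_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "",
                          stringsAsFactors = FALSE)
  meta_cols <- c("feature_id", "feature_level", "localization_probability")
  missing_meta <- setdiff(meta_cols, colnames(df))
  if (length(missing_meta)) {
    stop("missing required column(s): ", paste(missing_meta, collapse = ", "))
  }
  sample_cols <- setdiff(colnames(df), meta_cols)
  parts <- strsplit(sample_cols, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop("malformed sample column name(s): ",
         paste(sample_cols[bad], collapse = ", "))
  }
  samples <- data.frame(
    cell_line = vapply(parts, `[[`, "", 1L),
    treatment = vapply(parts, `[[`, "", 2L),
    replicate = as.integer(sub("^R", "", vapply(parts, `[[`, "", 3L))),
    stringsAsFactors = FALSE)
  intens <- as.matrix(df[, sample_cols, drop = FALSE])
  storage.mode(intens) <- "double"
  expression_table(df[, meta_cols], intens, samples)
}

#' Read a GMT gene-set library
#'
#' Standard GMT dialect: one term per line, tab-separated fields
#' `term<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated within a term.
#'
#' @param path GMT file
#' @return object of class `gene_set_library`: a named list of character
#'   member vectors, with term descriptions in the `descriptions` attribute
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(gene_set_library(list()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT line %d has %d field(s); at least 3 required",
                 bad[1L], lengths(fields)[bad[1L]]))
  }
  terms <- vapply(fields, `[[`, "", 1L)
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(members) <- terms
  gene_set_library(members, descriptions = stats::setNames(desc, terms))
}

#' Construct a gene-set library
#'
#' @param sets named list of character member vectors (term -> members)
#' @param descriptions optional named character vector of term descriptions
#' @return `gene_set_library`
#' @export
gene_set_library <- function(sets, descriptions = NULL) {
  if (length(sets)) {
    if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
      stop("every term needs a name")
    }
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      stop("empty term(s): ", paste(names(sets)[empty], collapse = ", "))
    }
    sets <- lapply(sets, function(m) unique(as.character(m)))
  }
  structure(sets, class = "gene_set_library", descriptions = descriptions)
}

#' Write a gene-set library in GMT format
#'
#' @param lib a `gene_set_library`
#' @param path output path
#' @return the path, invisibly
#' @export
write_gmt <- function(lib, path) {
  desc <- attr(lib, "descriptions")
  lines <- vapply(names(lib), function(tm) {
    d <- if (!is.null(desc) && tm %in% names(desc)) desc[[tm]] else "na"
    paste(c(tm, d, lib[[tm]]), collapse = "\t")
  }, "")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a dose-response viability matrix
#'
#' @param doses1,doses2 ascending non-negative dose vectors including 0
#'   (drug 1 indexes rows, drug 2 indexes columns)
#' @param response matrix of viability fractions (relative to the vehicle
#'   well), dimensions `length(doses1) x length(doses2)`
#' @param replicate_id identifier of the biological replicate
#' @return object of class `dose_matrix`
#' @export
dose_matrix <- function(doses1, doses2, response, replicate_id = 1L) {
  doses1 <- as.numeric(doses1); doses2 <- as.numeric(doses2)
  if (any(diff(doses1) <= 0) || any(diff(doses2) <= 0)) {
    stop("doses must be strictly ascending")
  }
  if (doses1[1L] != 0 || doses2[1L] != 0) {
    stop("dose vectors must include the zero (vehicle) dose first")
  }
  response <- as.matrix(response)
  if (nrow(response) != length(doses1) || ncol(response) != length(doses2)) {
    stop(sprintf("response is %d x %d but doses imply %d x %d",
                 nrow(response), ncol(response),
                 length(doses1), length(doses2)))
  }
  if (is.na(response[1L, 1L])) stop("vehicle (0, 0) well is missing")
  dimnames(response) <- list(.fmt_num(doses1), .fmt_num(doses2))
  structure(list(doses1 = doses1, doses2 = doses2, response = response,
                 replicate_id = replicate_id),
            class = "dose_matrix")
}

#' Read a dose-response matrix from CSV
#'
#' Layout: the header row carries drug-2 doses, the first column drug-1
#' doses, the top-left cell is a label. Non-numeric response cells are a hard
#' error naming the offending (row, column) coordinates; an absent (0, 0)
#' vehicle cell is a hard error.
#'
#' @param path CSV file
#' @param replicate_id identifier attached to the returned object
#' @return `dose_matrix`
#' @export
read_dose_matrix <- function(path, replicate_id = 1L) {
  df <- utils::read.csv(path, check.names = FALSE, header = TRUE,
                        na.strings = "", stringsAsFactors = FALSE)
  doses2 <- suppressWarnings(as.numeric(colnames(df)[-1L]))
  if (any(is.na(doses2))) stop("non-numeric drug-2 dose in header")
  doses1 <- suppressWarnings(as.numeric(df[[1L]]))
  if (any(is.na(doses1))) stop("non-numeric drug-1 dose in first column")
  resp <- df[, -1L, drop = FALSE]
  for (j in seq_along(resp)) {
    v <- suppressWarnings(as.numeric(resp[[j]]))
    bad <- which(is.na(v) & !is.na(resp[[j]]))
    if (length(bad)) {
      stop(sprintf("non-numeric response cell at row %d (dose1=%g), column %d (dose2=%g)",
                   bad[1L], doses1[bad[1L]], j, doses2[j]))
    }
    resp[[j]] <- v
  }
  dose_matrix(doses1, doses2, as.matrix(resp), replicate_id = replicate_id)
}

#' Write a dose-response matrix canonically
#'
#' @param dm a `dose_matrix`
#' @param path output CSV path
#' @return the path, invisibly
#' @export
write_dose_matrix <- function(dm, path) {
  df <- data.frame(dose = .fmt_num(dm$doses1), stringsAsFactors = FALSE)
  resp <- dm$response
  for (j in seq_along(dm$doses2)) df[[.fmt_num(dm$doses2[j])]] <- resp[, j]
  .write_delim_canonical(df, path, sep = ",")
}

#' Write result tables deterministically
#'
#' Writes each data.frame in `tables` as `<name>.tsv` under `out_dir` with
#' canonical formatting (fixed float encoding, stable row order as given), so
#' two runs on identical inputs produce byte-identical files.
#'
#' @param tables named list of data.frames
#' @param out_dir output directory (created if needed)
#' @return character vector of written paths, invisibly
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    .write_delim_canonical(as.data.frame(tables[[nm]]), p, sep = "\t")
    p
  }, "")
  invisible(paths)
}
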