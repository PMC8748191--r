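#' Construct a samples-by-taxa abundance table
#'
#' Lightweight container for compositional microbiome data at any taxonomic
#' level (the analyses in this package operate on phylum-level tables).
#' Values may be read counts or relative abundances; every balance computed
#' from the table is invariant to per-sample rescaling, so the two are
#' interchangeable downstream.
#'
#' @param values numeric matrix, samples in rows and taxa in columns. All
#'   entries must be non-negative and every row must have a positive sum.
#' @param sample_ids,taxon_ids optional character vectors; default to the
#'   dimnames of `values` or generated identifiers. Taxon ids must be unique.
#' @return An `abundance_table`: a numeric matrix with class attribute and
#'   row/column names set.
#' @export
abundance_table <- function(values, sample_ids = NULL, taxon_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("abundance values must not contain NA")
  if (any(values < 0)) stop("abundance values must be non-negative")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- sprintf("s%03d", seq_len(nrow(values)))
  }
  if (is.null(taxon_ids)) {
    taxon_ids <- colnames(values)
    if (is.null(taxon_ids)) taxon_ids <- sprintf("t%03d", seq_len(ncol(values)))
  }
  if (anyDuplicated(taxon_ids)) stop("taxon_ids must be unique")
  if (length(sample_ids) != nrow(values) || length(taxon_ids) != ncol(values))
    stop("id lengths do not match the value matrix")
  if (any(rowSums(values) <= 0))
    stop("every sample row must have a positive total abundance")
  dimnames(values) <- list(sample_ids, taxon_ids)
  class(values) <- c("abundance_table", "matrix", "array")
  values
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa\n", nrow(x), ncol(x)))
  invisible(x)
}

as_abundance_table <- function(x) {
  if (inherits(x, "abundance_table")) x else abundance_table(x)
}

#' Drop low-prevalence taxa
#'
#' Retains exactly the taxa whose fraction of zero entries across samples is
#' at most `max_zero_fraction`; the default reproduces the conventional rule
#' of discarding taxa with more than 20% zeros before balance selection.
#'
#' @param table an [abundance_table()] (or coercible matrix).
#' @param max_zero_fraction maximum tolerated proportion of zero entries per
#'   taxon, in \[0, 1\].
#' @return The filtered `abundance_table` (same samples, subset of taxa).
#' @export
filter_prevalence <- function(table, max_zero_fraction = 0.2) {
  table <- as_abundance_table(table)
  if (!is.numeric(max_zero_fraction) || length(max_zero_fraction) != 1 ||
      max_zero_fraction < 0 || max_zero_fraction > 1)
    stop("max_zero_fraction must be a single value in [0, 1]")
  zero_frac <- colMeans(table == 0)
  keep <- zero_frac <= max_zero_fraction
  if (!any(keep)) stop("prevalence filter removed all taxa")
  abundance_table(unclass(table)[, keep, drop = FALSE])
}

#' Replace zero abundances with a pseudocount
#'
#' Geometric means are undefined at zero, so zeros must be imputed before any
#' balance is computed. Count tables get the additive pseudocount itself;
#' tables of proportions (rows summing to ~1) get `pseudocount / depth`, the
#' proportion-scale equivalent at the assumed sequencing depth. Non-zero
#' entries are never touched, so the operation is idempotent.
#'
#' @param table an [abundance_table()].
#' @param pseudocount positive replacement value on the count scale.
#' @param type `"auto"` detects proportions by row sums within 1e-6 of 1;
#'   `"counts"`/`"proportions"` force the interpretation.
#' @param depth assumed read depth used to scale the pseudocount for
#'   proportion tables.
#' @return The `abundance_table` with zeros replaced.
#' @export
replace_zeros <- function(table, pseudocount = 0.5,
                          type = c("auto", "counts", "proportions"),
                          depth = 5000) {
  table <- as_abundance_table(table)
  type <- match.arg(type)
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stop("pseudocount must be a single positive value")
  if (type == "auto") {
    type <- if (all(abs(rowSums(table) - 1) < 1e-6)) "proportions" else "counts"
  }
  repl <- if (type == "proportions") pseudocount / depth else pseudocount
  out <- unclass(table)
  out[out == 0] <- repl
  abundance_table(out, rownames(table), colnames(table))
}

#' Define a balance signature
#'
#' A balance is the log-ratio of the geometric mean abundance of a numerator
#' taxon group A against a denominator group B. Positive balance values mean
#' the A taxa are jointly more abundant than the B taxa. The optional
#' isometric-log-ratio normalization `sqrt(|A||B| / (|A|+|B|))` rescales the
#' statistic to the canonical ilr coordinate; it is off by default so balance
#' values stay on the plain log-ratio scale.
#'
#' @param numerator,denominator disjoint non-empty character vectors of taxon
#'   ids (groups A and B).
#' @param log_base one of `"e"`, `"2"`, `"10"`.
#' @param use_ilr_coefficient logical; apply the ilr normalization
#'   coefficient.
#' @param score optional association score (R-squared) attached by the
#'   selection routines.
#' @return A `balance_signature` object.
#' @export
balance_signature <- function(numerator, denominator,
                              log_base = c("e", "2", "10"),
                              use_ilr_coefficient = FALSE, score = NA_real_) {
  numerator <- as.character(numerator)
  denominator <- as.character(denominator)
  log_base <- match.arg(log_base)
  if (length(numerator) < 1 || length(denominator) < 1)
    stop("both numerator and denominator must be non-empty")
  if (length(intersect(numerator, denominator)) > 0)
    stop("numerator and denominator must be disjoint taxon sets")
  if (anyDuplicated(numerator) || anyDuplicated(denominator))
    stop("taxon sets must not contain duplicates")
  structure(
    list(numerator = numerator, denominator = denominator,
         log_base = log_base, use_ilr_coefficient = use_ilr_coefficient,
         score = score),
    class = "balance_signature"
  )
}

#' @export
print.balance_signature <- function(x, ...) {
  cat("<balance_signature>\n")
  cat("  A (numerator):  ", paste(x$numerator, collapse = ", "), "\n")
  cat("  B (denominator):", paste(x$denominator, collapse = ", "), "\n")
  cat(sprintf("  log base %s, ilr coefficient %s",
              x$log_base, if (x$use_ilr_coefficient) "on" else "off"))
  if (!is.na(x$score)) cat(sprintf(", score (R^2) %.4f", x$score))
  cat("\n")
  invisible(x)
}

signature_size <- function(sig) length(sig$numerator) + length(sig$denominator)

log_base_value <- function(log_base) {
  switch(log_base, "e" = exp(1), "2" = 2, "10" = 10)
}

#' Compute per-sample balance values
#'
#' For each sample `i` the balance is
#' `c * log( gmean(x[i, A]) / gmean(x[i, B]) )`, where `gmean` is the
#' geometric mean and `c` the optional ilr coefficient (see
#' [balance_signature()]). The statistic only involves ratios within a
#' sample, so it is invariant to closure: counts, proportions, or any
#' per-sample rescaling give identical values.
#'
#' @param table an [abundance_table()], strictly positive on the signature
#'   taxa (apply [replace_zeros()] first if needed).
#' @param sig a [balance_signature()].
#' @return Named numeric vector of balance values, one per sample.
#' @export
compute_balance <- function(table, sig) {
  table <- as_abundance_table(table)
  taxa <- c(sig$numerator, sig$denominator)
  missing <- setdiff(taxa, colnames(table))
  if (length(missing) > 0)
    stop("signature taxa absent from table: ", paste(missing, collapse = ", "))
  sub <- unclass(table)[, taxa, drop = FALSE]
  if (any(sub <= 0)) {
    bad <- which(sub <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive abundance for sample '%s', taxon '%s'; apply replace_zeros() first",
      rownames(sub)[bad[1]], colnames(sub)[bad[2]]))
  }
  lg <- log(sub)
  a <- rowMeans(lg[, sig$numerator, drop = FALSE])
  b <- rowMeans(lg[, sig$denominator, drop = FALSE])
  k1 <- length(sig$numerator); k2 <- length(sig$denominator)
  cc <- if (isTRUE(sig$use_ilr_coefficient)) sqrt(k1 * k2 / (k1 + k2)) else 1
  out <- cc * (a - b) / log(log_base_value(sig$log_base))
  names(out) <- rownames(table)
  out
}
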