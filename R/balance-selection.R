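#' Score a balance against a continuous response
#'
#' Association criterion used throughout the forward search: the coefficient
#' of determination (R-squared) of an ordinary least-squares fit of the
#' response on an intercept, optional covariates, and the balance values.
#'
#' @param balance_values numeric vector of per-sample balance values.
#' @param response numeric response (e.g. BMI in kg/m^2).
#' @param covariates optional numeric matrix of adjustment covariates.
#' @return R-squared in \[0, 1\]. A constant response returns 0; a constant
#'   balance vector is a degenerate regressor and raises an error.
#' @export
score_balance <- function(balance_values, response, covariates = NULL) {
  if (length(balance_values) != length(response))
    stop("balance_values and response must have equal length")
  if (stats::sd(balance_values) == 0)
    stop("degenerate regressor: balance vector is constant")
  tss <- sum((response - mean(response))^2)
  if (tss == 0) return(0)
  X <- cbind(1, covariates, balance_values)
  fit <- stats::.lm.fit(X, response)
  rss <- sum(fit$residuals^2)
  max(0, min(1, 1 - rss / tss))
}

# Coefficient sign of the balance column in the scoring fit; used to orient
# the first pair so that its balance associates positively with the response.
balance_coef_sign <- function(balance_values, response, covariates = NULL) {
  X <- cbind(1, covariates, balance_values)
  fit <- stats::.lm.fit(X, response)
  sign(fit$coefficients[ncol(X)])
}

#' Find the single-taxon pair whose balance best predicts the response
#'
#' Exhaustive search over all taxon pairs; the winning pair is oriented so
#' its balance is positively associated with the response, and exact score
#' ties are broken lexicographically by taxon id (numerator side first).
#'
#' @inheritParams forward_select
#' @return A [balance_signature()] with one taxon per side and the achieved
#'   R-squared in `$score`.
#' @export
select_first_pair <- function(table, response, covariates = NULL,
                              log_base = "e", use_ilr_coefficient = FALSE) {
  table <- as_abundance_table(table)
  if (ncol(table) < 2) stop("need at least two taxa to form a balance")
  if (any(table <= 0)) stop("table must be strictly positive; apply replace_zeros() first")
  taxa <- sort(colnames(table))
  L <- log(unclass(table)[, taxa, drop = FALSE])
  cc <- if (use_ilr_coefficient) sqrt(1 / 2) else 1
  lb <- log(log_base_value(log_base))
  best <- list(score = -Inf, a = NULL, b = NULL)
  for (i in seq_len(length(taxa) - 1)) {
    for (j in seq(i + 1, length(taxa))) {
      bal <- cc * (L[, i] - L[, j]) / lb
      if (stats::sd(bal) == 0) next
      sc <- score_balance(bal, response, covariates)
      if (sc > best$score) {
        if (balance_coef_sign(bal, response, covariates) >= 0) {
          best <- list(score = sc, a = taxa[i], b = taxa[j])
        } else {
          best <- list(score = sc, a = taxa[j], b = taxa[i])
        }
      }
    }
  }
  if (!is.finite(best$score))
    stop("no valid taxon pair found (all candidate balances degenerate)")
  balance_signature(best$a, best$b, log_base = log_base,
                    use_ilr_coefficient = use_ilr_coefficient,
                    score = best$score)
}

#' Forward selection of a predictive balance
#'
#' Forward regression in balance space: starting from the best single pair
#' ([select_first_pair()]), every remaining taxon is assessed for inclusion on
#' either side of the balance; the single best addition is accepted while it
#' improves the R-squared by at least `min_improvement`, up to `max_size`
#' taxa in total. Candidate ties are broken lexicographically by taxon id
#' with the numerator side preferred; degenerate candidates are skipped and
#' recorded as `NA` in the trace.
#'
#' @param table strictly positive [abundance_table()].
#' @param response numeric response vector, one value per sample.
#' @param max_size maximum total number of taxa in the signature.
#' @param min_improvement minimum absolute R-squared gain to accept a step.
#' @param covariates optional covariate matrix passed to [score_balance()].
#' @param log_base,use_ilr_coefficient balance conventions, see
#'   [balance_signature()].
#' @return A list with `signature` (a [balance_signature()]), `trace` (a
#'   `selection_trace` with the accepted path and all candidate scores), and
#'   `path` (ordered `(taxon, side)` additions enabling truncation to any
#'   intermediate size).
#' @export
forward_select <- function(table, response, max_size = 8,
                           min_improvement = 1e-4, covariates = NULL,
                           log_base = "e", use_ilr_coefficient = FALSE) {
  table <- as_abundance_table(table)
  first <- select_first_pair(table, response, covariates,
                             log_base = log_base,
                             use_ilr_coefficient = use_ilr_coefficient)
  taxa <- sort(colnames(table))
  L <- log(unclass(table)[, taxa, drop = FALSE])
  lb <- log(log_base_value(log_base))
  A <- first$numerator; B <- first$denominator
  score <- first$score
  path <- list(list(taxon = A, side = "A"), list(taxon = B, side = "B"))
  steps <- data.frame(added_taxon = c(A, B), side = c("A", "B"),
                      score_after = c(NA_real_, score),
                      stringsAsFactors = FALSE)
  candidate_scores <- list()
  sumA <- L[, A]; sumB <- L[, B]
  repeat {
    if (length(A) + length(B) >= max_size) break
    remaining <- setdiff(taxa, c(A, B))
    if (length(remaining) == 0) break
    kA <- length(A); kB <- length(B)
    cand <- data.frame(taxon = rep(remaining, each = 2),
                       side = rep(c("A", "B"), length(remaining)),
                       score = NA_real_, stringsAsFactors = FALSE)
    best_i <- 0L; best_sc <- -Inf
    for (r in seq_len(nrow(cand))) {
      t <- cand$taxon[r]
      if (cand$side[r] == "A") {
        bal <- ((sumA + L[, t]) / (kA + 1) - sumB / kB)
        cc <- if (use_ilr_coefficient) sqrt((kA + 1) * kB / (kA + 1 + kB)) else 1
      } else {
        bal <- (sumA / kA - (sumB + L[, t]) / (kB + 1))
        cc <- if (use_ilr_coefficient) sqrt(kA * (kB + 1) / (kA + kB + 1)) else 1
      }
      bal <- cc * bal / lb
      if (stats::sd(bal) == 0) next  # degenerate candidate: skip, leave NA
      sc <- score_balance(bal, response, covariates)
      cand$score[r] <- sc
      # rows are ordered (taxon lexicographic, A before B), so strict
      # improvement implements the documented tie-break
      if (sc > best_sc) { best_sc <- sc; best_i <- r }
    }
    candidate_scores[[length(candidate_scores) + 1L]] <- cand
    if (best_i == 0L || !(best_sc - score >= min_improvement)) break
    t <- cand$taxon[best_i]
    if (cand$side[best_i] == "A") { A <- c(A, t); sumA <- sumA + L[, t] }
    else { B <- c(B, t); sumB <- sumB + L[, t] }
    score <- best_sc
    path[[length(path) + 1L]] <- list(taxon = t, side = cand$side[best_i])
    steps <- rbind(steps, data.frame(added_taxon = t, side = cand$side[best_i],
                                     score_after = score, stringsAsFactors = FALSE))
  }
  sig <- balance_signature(A, B, log_base = log_base,
                           use_ilr_coefficient = use_ilr_coefficient,
                           score = score)
  trace <- structure(list(steps = steps, candidate_scores = candidate_scores),
                     class = "selection_trace")
  list(signature = sig, trace = trace, path = path)
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  print(x$steps)
  invisible(x)
}

# Rebuild the signature from the first `size` path entries.
truncate_path <- function(path, size, log_base = "e",
                          use_ilr_coefficient = FALSE) {
  size <- min(size, length(path))
  ent <- path[seq_len(size)]
  A <- vapply(Filter(function(e) e$side == "A", ent), `[[`, "", "taxon")
  B <- vapply(Filter(function(e) e$side == "B", ent), `[[`, "", "taxon")
  balance_signature(A, B, log_base = log_base,
                    use_ilr_coefficient = use_ilr_coefficient)
}

signature_key <- function(sig) {
  paste0("{", paste(sort(sig$numerator), collapse = ","), "}/{",
         paste(sort(sig$denominator), collapse = ","), "}")
}

#' Cross-validated signature size and robustness summaries
#'
#' Repeated k-fold cross-validation around [forward_select()]. Each training
#' split is searched up to `max_size`; held-out mean squared error of the
#' balance regression is recorded for every signature size along the path.
#' The reported size is chosen by the one-standard-error rule on mean
#' held-out MSE, and the final signature is the full-data forward path
#' truncated to that size. Robustness summaries record how often each taxon,
#' and each complete balance, was selected across cross-validation fits.
#'
#' @inheritParams forward_select
#' @param folds number of folds (>= 2).
#' @param repeats number of repetitions of the fold split.
#' @param rng_seed integer seed controlling fold assignment.
#' @return A list with `optimal_size`, `signature`, `trace` (full-data
#'   trace), and `robustness` (a `robustness_table` with
#'   `per_taxon_frequency`, `per_balance_frequency`, `cv_score_by_size`).
#' @export
cross_validate_signature <- function(table, response, folds = 5, repeats = 10,
                                     max_size = 8, min_improvement = 1e-4,
                                     covariates = NULL, rng_seed = 1,
                                     log_base = "e",
                                     use_ilr_coefficient = FALSE) {
  table <- as_abundance_table(table)
  if (folds < 2) stop("folds must be at least 2")
  n <- nrow(table)
  sizes <- seq(2L, max_size)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)
  fit_paths <- list()
  mse <- matrix(NA_real_, nrow = 0, ncol = length(sizes))
  for (rep_i in seq_len(repeats)) {
    assign_f <- sample(rep(seq_len(folds), length.out = n))
    for (f in seq_len(folds)) {
      test <- which(assign_f == f); train <- which(assign_f != f)
      y_tr <- response[train]
      if (stats::sd(y_tr) == 0) {
        warning("skipping fold with constant training response")
        next
      }
      cov_tr <- if (is.null(covariates)) NULL else covariates[train, , drop = FALSE]
      cov_te <- if (is.null(covariates)) NULL else covariates[test, , drop = FALSE]
      fs <- forward_select(unclass(table)[train, , drop = FALSE], y_tr,
                           max_size = max_size,
                           min_improvement = min_improvement,
                           covariates = cov_tr,
                           log_base = log_base,
                           use_ilr_coefficient = use_ilr_coefficient)
      fit_paths[[length(fit_paths) + 1L]] <- fs$path
      row <- rep(NA_real_, length(sizes))
      for (si in seq_along(sizes)) {
        sig_s <- truncate_path(fs$path, sizes[si], log_base,
                               use_ilr_coefficient)
        bal_tr <- compute_balance(unclass(table)[train, , drop = FALSE], sig_s)
        bal_te <- compute_balance(unclass(table)[test, , drop = FALSE], sig_s)
        Xtr <- cbind(1, cov_tr, bal_tr)
        Xte <- cbind(1, cov_te, bal_te)
        beta <- stats::.lm.fit(Xtr, y_tr)$coefficients
        pred <- drop(Xte %*% beta)
        row[si] <- mean((response[test] - pred)^2)
      }
      mse <- rbind(mse, row)
    }
  }
  if (nrow(mse) == 0) stop("no usable cross-validation fits")
  mean_mse <- colMeans(mse)
  se_mse <- apply(mse, 2, stats::sd) / sqrt(nrow(mse))
  i_min <- which.min(mean_mse)
  thresh <- mean_mse[i_min] + se_mse[i_min]
  optimal_size <- sizes[which(mean_mse <= thresh)[1]]

  full <- forward_select(table, response, max_size = max_size,
                         min_improvement = min_improvement,
                         covariates = covariates, log_base = log_base,
                         use_ilr_coefficient = use_ilr_coefficient)
  final_sig <- truncate_path(full$path, optimal_size, log_base,
                             use_ilr_coefficient)
  final_sig$score <- score_balance(compute_balance(table, final_sig),
                                   response, covariates)

  # robustness is summarized over each fold's complete accepted signature
  # (its own stopping point), matching how fold-optimal balances of varying
  # sizes are tabulated in selection-frequency displays
  taxa <- colnames(table)
  sel_mat <- vapply(fit_paths, function(p) {
    s <- truncate_path(p, length(p), log_base, use_ilr_coefficient)
    taxa %in% c(s$numerator, s$denominator)
  }, logical(length(taxa)))
  per_taxon <- rowMeans(sel_mat)
  names(per_taxon) <- taxa
  keys <- vapply(fit_paths, function(p) {
    signature_key(truncate_path(p, length(p), log_base,
                                use_ilr_coefficient))
  }, "")
  per_balance <- sort(table(keys) / length(keys), decreasing = TRUE)
  per_balance <- stats::setNames(as.numeric(per_balance), names(per_balance))
  robustness <- structure(
    list(per_taxon_frequency = sort(per_taxon, decreasing = TRUE),
         per_balance_frequency = per_balance,
         cv_score_by_size = data.frame(size = sizes, mean_mse = mean_mse,
                                       se_mse = se_mse, n_fits = nrow(mse))),
    class = "robustness_table"
  )
  list(optimal_size = optimal_size, signature = final_sig,
       trace = full$trace, robustness = robustness)
}

#' @export
print.robustness_table <- function(x, ...) {
  cat("<robustness_table>\n  per-taxon selection frequency (top):\n")
  print(utils::head(round(x$per_taxon_frequency, 3), 8))
  cat("  held-out MSE by signature size:\n")
  print(x$cv_score_by_size, row.names = FALSE)
  invisible(x)
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
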