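#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis: input locations (or the
#' synthetic-cohort specification), the prevalence and GM-mask thresholds,
#' the cross-validation design, seed definitions, the contrasts to test per
#' seed model, and the TFCE/permutation settings.
#'
#' @param output_dir directory for the report bundle.
#' @param abundance_tsv,phenotype_tsv,volume_manifest input paths; leave
#'   `NULL` to generate a synthetic cohort instead.
#' @param synthetic logical; generate inputs with [gen_microbiome()] and
#'   [gen_volume_stack()].
#' @param rng_seed master seed; stage seeds are derived from it.
#' @param cohort a [cohort_spec()] for synthetic generation (default built
#'   from `rng_seed`).
#' @param volumes a [volume_spec()] for synthetic generation.
#' @param prevalence_threshold maximum zero fraction per taxon (default 0.20).
#' @param pseudocount zero replacement on the count scale.
#' @param cv_folds,cv_repeats,max_signature_size cross-validation design.
#' @param gm_threshold GM mask threshold (default 0.2).
#' @param seeds named list of [seed_spec()]s; each seed is modelled with the
#'   other one as covariate.
#' @param contrasts contrast names to test: a character vector (applied to
#'   every seed model), a named list keyed by seed name, or `NULL` to test
#'   all pairwise interaction contrasts.
#' @param tfce a [tfce_params()].
#' @param n_permutations permutations for FWE inference (500 desk-scale
#'   default; 5000 for full-study inference).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir,
                            abundance_tsv = NULL, phenotype_tsv = NULL,
                            volume_manifest = NULL,
                            synthetic = is.null(abundance_tsv),
                            rng_seed = 1,
                            cohort = NULL, volumes = NULL,
                            prevalence_threshold = 0.2, pseudocount = 0.5,
                            cv_folds = 5, cv_repeats = 10,
                            max_signature_size = 8,
                            gm_threshold = 0.2,
                            seeds = default_seeds(),
                            contrasts = NULL,
                            tfce = tfce_params(),
                            n_permutations = 500) {
  if (synthetic) {
    if (is.null(cohort)) cohort <- cohort_spec(rng_seed = rng_seed)
    if (is.null(volumes)) volumes <- volume_spec(rng_seed = rng_seed + 1L)
  }
  structure(
    list(output_dir = output_dir, abundance_tsv = abundance_tsv,
         phenotype_tsv = phenotype_tsv, volume_manifest = volume_manifest,
         synthetic = synthetic, rng_seed = as.integer(rng_seed),
         cohort = cohort, volumes = volumes,
         prevalence_threshold = prevalence_threshold,
         pseudocount = pseudocount,
         cv_folds = cv_folds, cv_repeats = cv_repeats,
         max_signature_size = max_signature_size,
         gm_threshold = gm_threshold, seeds = seeds, contrasts = contrasts,
         tfce = tfce, n_permutations = n_permutations),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; seed
#' definitions may be given as `seeds: {MH: {coords: [[4,2,-12],[-4,2,-12]],
#' radius: 2}, ...}`.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("output_dir", "abundance_tsv", "phenotype_tsv",
                        "volume_manifest", "synthetic", "rng_seed",
                        "prevalence_threshold", "pseudocount", "cv_folds",
                        "cv_repeats", "max_signature_size", "gm_threshold",
                        "contrasts", "n_permutations"))]
  if (!is.null(y$seeds)) {
    args$seeds <- lapply(names(y$seeds), function(nm) {
      s <- y$seeds[[nm]]
      seed_spec(nm, do.call(rbind, s$coords), radius = s$radius %||% 2)
    })
    names(args$seeds) <- names(y$seeds)
  }
  if (!is.null(y$tfce))
    args$tfce <- do.call(tfce_params, y$tfce)
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full gut-brain covariance pipeline
#'
#' Stages, mirroring the analysis order: (1) microbiome signature -
#' prevalence filter, zero replacement, cross-validated forward balance
#' selection; (2) stratification - balance evaluation, median split of the
#' obese subgroup, cognitive/mood group comparisons; (3) structural
#' covariance - GM mask, seed extraction, sequential orthogonalization, one
#' interaction GLM per seed (with the other hypothalamic seed as covariate);
#' (4) inference - TFCE, max-statistic permutation FWE, cluster/peak tables.
#' All outputs are written under `config$output_dir` and the run is fully
#' reproducible from `config$rng_seed`.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the fitted signature, stratified
#'   phenotypes, group comparisons, and one `fwe_result` per seed model and
#'   contrast.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  # -- inputs ---------------------------------------------------------------
  dat <- stage("input", {
    if (config$synthetic) {
      gen_microbiome(config$cohort)
    } else {
      tab <- utils::read.delim(config$abundance_tsv, row.names = 1,
                               check.names = FALSE)
      list(table = abundance_table(as.matrix(tab)),
           phenotypes = utils::read.delim(config$phenotype_tsv,
                                          stringsAsFactors = FALSE))
    }
  })
  # -- signature ------------------------------------------------------------
  sig_fit <- stage("signature", {
    filtered <- filter_prevalence(dat$table, config$prevalence_threshold)
    positive <- replace_zeros(filtered, config$pseudocount)
    cv <- cross_validate_signature(positive, dat$phenotypes$bmi,
                                   folds = config$cv_folds,
                                   repeats = config$cv_repeats,
                                   max_size = config$max_signature_size,
                                   rng_seed = config$rng_seed + 17L)
    cv$balance <- compute_balance(positive, cv$signature)
    cv$positive_table <- positive
    cv
  })
  pheno <- dat$phenotypes
  pheno$balance_value <- unname(sig_fit$balance)
  balance_bmi_r <- stats::cor(pheno$balance_value, pheno$bmi)
  # orient so higher balance tracks higher BMI, matching the convention that
  # the numerator taxa mark the obesity-associated side
  if (balance_bmi_r < 0) {
    sig <- sig_fit$signature
    sig_fit$signature <- balance_signature(sig$denominator, sig$numerator,
                                           log_base = sig$log_base,
                                           use_ilr_coefficient =
                                             sig$use_ilr_coefficient,
                                           score = sig$score)
    pheno$balance_value <- -pheno$balance_value
    balance_bmi_r <- -balance_bmi_r
  }
  # -- stratification -------------------------------------------------------
  pheno <- stage("stratify", stratify_by_median(pheno))
  comparisons <- stage("group comparisons", {
    rbind(
      comparison_row(pheno, "stroop_interference",
                     c("obese-dysbiosis", "obese-no-dysbiosis")),
      comparison_row(pheno, "stroop_interference",
                     c("obese-dysbiosis", "obese-no-dysbiosis"),
                     covariates = "age"),
      comparison_row(pheno, "stroop_interference",
                     c("obese-dysbiosis", "non-obese")),
      comparison_row(pheno, "phq9",
                     c("obese-dysbiosis", "obese-no-dysbiosis")),
      comparison_row(pheno, "phq9", c("obese-dysbiosis", "non-obese"))
    )
  })
  # -- volumes --------------------------------------------------------------
  stack <- stage("volumes", {
    if (config$synthetic) {
      ph <- pheno
      gen_volume_stack(config$volumes, ph)
    } else {
      read_volume_stack(config$volume_manifest)
    }
  })
  mask <- stage("gm mask", make_gm_mask(stack, config$gm_threshold))
  ggmv <- global_gmv(stack)
  seed_values <- lapply(config$seeds, function(s) extract_seed(stack, s))
  # -- covariance models + inference ---------------------------------------
  results <- list()
  peak_rows <- list()
  for (seed_name in names(config$seeds)) {
    other <- setdiff(names(config$seeds), seed_name)[1]
    design <- design_matrix(age = pheno$age, sex = pheno$sex,
                            global_gmv = ggmv,
                            other_seed = seed_values[[other]],
                            seed = seed_values[[seed_name]],
                            group = pheno$stratum)
    fit <- stage(paste0("glm ", seed_name),
                 fit_interaction_glm(stack, design, mask))
    wanted <- config$contrasts
    if (is.list(wanted)) wanted <- wanted[[seed_name]]
    wanted <- wanted %||% names(fit$contrasts)
    wanted <- intersect(wanted, names(fit$contrasts))
    for (ctr in wanted) {
      fwe <- stage(paste0("fwe ", seed_name, " ", ctr),
                   permutation_fwe(fit, ctr, params = config$tfce,
                                   scheme = permutation_scheme(
                                     config$n_permutations,
                                     rng_seed = config$rng_seed + 101L)))
      key <- paste(seed_name, ctr, sep = ".")
      results[[key]] <- fwe
      ct <- cluster_table(fwe)
      if (nrow(ct) > 0) {
        ct <- cbind(seed = seed_name, contrast = ctr, ct)
        peak_rows[[key]] <- ct
      }
      write_stat_maps(fwe, out_dir, key)
    }
  }
  peaks <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(seed = character(), contrast = character(),
               tail = character(), peak_x = numeric(), peak_y = numeric(),
               peak_z = numeric(), t = numeric(), tfce = numeric(),
               p_fwe = numeric(), k_extent = integer())
  # -- report bundle --------------------------------------------------------
  stage("report", {
    sig <- sig_fit$signature
    jsonlite::write_json(
      list(numerator = sig$numerator, denominator = sig$denominator,
           log_base = sig$log_base,
           coefficient = if (sig$use_ilr_coefficient) "ilr" else "none",
           score = sig$score, optimal_size = sig_fit$optimal_size,
           balance_bmi_r = balance_bmi_r,
           obese_median = as.numeric(attr(pheno, "balance_median"))),
      file.path(out_dir, "signature.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rob <- sig_fit$robustness
    utils::write.table(
      data.frame(taxon = names(rob$per_taxon_frequency),
                 selection_frequency = as.numeric(rob$per_taxon_frequency)),
      file.path(out_dir, "robustness_taxa.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rob$cv_score_by_size,
                       file.path(out_dir, "robustness_cv.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pheno, file.path(out_dir, "phenotypes_stratified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(comparisons,
                       file.path(out_dir, "group_comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(peaks, file.path(out_dir, "peaks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(
      list(rng_seed = config$rng_seed,
           n_permutations = config$n_permutations,
           prevalence_threshold = config$prevalence_threshold,
           gm_threshold = config$gm_threshold,
           cv = list(folds = config$cv_folds, repeats = config$cv_repeats,
                     max_size = config$max_signature_size),
           tfce = list(E = config$tfce$E, H = config$tfce$H,
                       n_steps = config$tfce$n_steps,
                       connectivity = config$tfce$connectivity),
           strata_sizes = as.list(table(pheno$stratum))),
      file.path(out_dir, "run_log.yaml"))
  })
  invisible(list(signature = sig_fit$signature,
                 optimal_size = sig_fit$optimal_size,
                 robustness = sig_fit$robustness,
                 balance_bmi_r = balance_bmi_r,
                 phenotypes = pheno, comparisons = comparisons,
                 fwe = results, peaks = peaks, mask = mask,
                 truth = attr(stack, "truth")))
}

comparison_row <- function(pheno, variable, groups, covariates = NULL) {
  cg <- compare_groups(pheno, variable, groups, covariates = covariates)
  data.frame(variable = variable, group1 = groups[1], group2 = groups[2],
             adjusted = paste(covariates %||% "", collapse = "+"),
             n1 = cg$summary$n[1], n2 = cg$summary$n[2],
             mean1 = cg$summary$mean[1], mean2 = cg$summary$mean[2],
             sd1 = cg$summary$sd[1], sd2 = cg$summary$sd[2],
             t = cg$t, df = cg$df, p = cg$p,
             stringsAsFactors = FALSE)
}

#' Cluster/peak table from an FWE result
#'
#' Connected components (at the TFCE connectivity) of the voxels significant
#' at `p_fwe < alpha`, separately per tail, with the peak (maximum-TFCE)
#' voxel's mm coordinates, t, TFCE, p_fwe, and cluster extent.
#'
#' @param fwe an `fwe_result`.
#' @param alpha significance threshold (default 0.05).
#' @return Data frame, one row per cluster.
#' @export
cluster_table <- function(fwe, alpha = 0.05) {
  stopifnot(inherits(fwe, "fwe_result"))
  fit <- fwe$fit
  rows <- list()
  for (tail in c("pos", "neg")) {
    p <- if (tail == "pos") fwe$p_fwe_pos else fwe$p_fwe_neg
    sig <- !is.na(p) & p < alpha
    if (!any(sig)) next
    lab <- array(label_components_cpp(as.vector(sig), fit$dims,
                                      fwe$params$connectivity), fit$dims)
    tf <- abs(fwe$tfce_map$values)
    for (l in seq_len(max(lab))) {
      vox <- which(lab == l)
      peak <- vox[which.max(tf[vox])]
      pc <- arrayInd(peak, fit$dims)
      mm <- drop(voxel_to_mm(fit$affine, pc))
      rows[[length(rows) + 1L]] <- data.frame(
        tail = tail, peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
        t = fwe$t_map$values[peak], tfce = tf[peak], p_fwe = p[peak],
        k_extent = length(vox))
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(tail = character(), peak_x = numeric(), peak_y = numeric(),
               peak_z = numeric(), t = numeric(), tfce = numeric(),
               p_fwe = numeric(), k_extent = integer())
}

write_stat_maps <- function(fwe, out_dir, key) {
  fit <- fwe$fit
  sf <- fit$affine
  sf[1:3, 4] <- sf[1:3, 4] + sf[1:3, 1:3] %*% rep(1, 3)
  wr <- function(arr, nm) {
    arr[is.na(arr)] <- 0
    im <- RNifti::asNifti(arr)
    im <- RNifti::`sform<-`(im, structure(sf, code = 2L))
    RNifti::writeNifti(im, file.path(out_dir, sprintf("%s_%s.nii", key, nm)))
  }
  wr(fwe$t_map$values, "t")
  wr(fwe$tfce_map$values, "tfce")
  wr(fwe$p_fwe_pos, "pfwe_pos")
  wr(fwe$p_fwe_neg, "pfwe_neg")
}
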