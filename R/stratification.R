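#' Split subjects with obesity by the median of their balance values
#'
#' The cohort's BMI-associated balance is evaluated in the obese subgroup and
#' its median taken; obese subjects strictly above the median form the
#' gut-dysbiosis stratum, those at or below it the no-dysbiosis stratum, and
#' non-obese subjects are left untouched. Values exactly at the median go to
#' the no-dysbiosis side by default (`ties = "lower"`), which is the
#' conservative reading of a higher-vs-lower split; `ties = "upper"` assigns
#' them to the dysbiosis stratum instead.
#'
#' @param pheno data frame with at least `obesity` (`"obese"`/`"non-obese"`)
#'   and `balance_value` columns.
#' @param ties side receiving subjects whose balance equals the median.
#' @return `pheno` with a `stratum` factor
#'   (`non-obese`, `obese-no-dysbiosis`, `obese-dysbiosis`) and the obese
#'   median stored in `attr(, "balance_median")`.
#' @export
stratify_by_median <- function(pheno, ties = c("lower", "upper")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(pheno),
            all(c("obesity", "balance_value") %in% names(pheno)))
  obese <- pheno$obesity == "obese"
  if (!any(obese)) stop("no obese subjects to stratify")
  if (anyNA(pheno$balance_value[obese]))
    stop("balance_value missing for some obese subjects")
  med <- stats::median(pheno$balance_value[obese])
  stratum <- rep("non-obese", nrow(pheno))
  if (ties == "lower") {
    dys <- obese & pheno$balance_value > med
  } else {
    dys <- obese & pheno$balance_value >= med
  }
  stratum[obese] <- ifelse(dys[obese], "obese-dysbiosis", "obese-no-dysbiosis")
  pheno$stratum <- factor(stratum, levels = c("non-obese",
                                              "obese-no-dysbiosis",
                                              "obese-dysbiosis"))
  attr(pheno, "balance_median") <- med
  pheno
}

#' Two-group comparison of a phenotype variable
#'
#' Independent-samples t-test between two strata, pooled-variance by default
#' (the variables compared here were screened for variance homogeneity);
#' Welch correction available via `var_equal = FALSE`. With covariates the
#' comparison becomes an ANCOVA: the reported t and p are for the group
#' coefficient in a linear model of the variable on group plus covariates.
#'
#' @param pheno stratified data frame (see [stratify_by_median()]).
#' @param variable name of the numeric column to compare.
#' @param groups character pair of stratum (or group-column) labels.
#' @param covariates optional character vector of covariate column names.
#' @param group_col column holding the group labels, default `"stratum"`.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE) t-test.
#' @return A list with `t`, `df`, `p`, and a `summary` data frame of n,
#'   mean, and sd per group.
#' @export
compare_groups <- function(pheno, variable, groups, covariates = NULL,
                           group_col = "stratum", var_equal = TRUE) {
  stopifnot(is.data.frame(pheno), variable %in% names(pheno),
            group_col %in% names(pheno), length(groups) == 2)
  g <- as.character(pheno[[group_col]])
  keep <- g %in% groups & !is.na(pheno[[variable]])
  dat <- pheno[keep, , drop = FALSE]
  g <- factor(as.character(dat[[group_col]]), levels = groups)
  y <- dat[[variable]]
  if (any(table(g) < 2)) stop("need at least 2 subjects per group")
  sum_tab <- do.call(rbind, lapply(groups, function(gr) {
    v <- y[g == gr]
    data.frame(group = gr, n = length(v), mean = mean(v), sd = stats::sd(v))
  }))
  if (stats::sd(y[g == groups[1]]) == 0 && stats::sd(y[g == groups[2]]) == 0 &&
      mean(y[g == groups[1]]) == mean(y[g == groups[2]]))
    return(list(t = 0, df = length(y) - 2, p = 1, summary = sum_tab))
  if (is.null(covariates)) {
    tt <- stats::t.test(y[g == groups[1]], y[g == groups[2]],
                        var.equal = var_equal)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value, summary = sum_tab)
  } else {
    stopifnot(all(covariates %in% names(dat)))
    X <- stats::model.matrix(
      stats::reformulate(c(covariates, "g"), intercept = TRUE),
      data = cbind(dat, g = g))
    fit <- stats::lm.fit(X, y)
    df <- length(y) - fit$rank
    sigma2 <- sum(fit$residuals^2) / df
    XtXinv <- chol2inv(chol(crossprod(X)))
    j <- ncol(X)  # group indicator enters last
    se <- sqrt(sigma2 * XtXinv[j, j])
    tval <- unname(-fit$coefficients[j] / se)  # sign: groups[1] - groups[2]
    res <- list(t = tval, df = df,
                p = 2 * stats::pt(-abs(tval), df), summary = sum_tab)
  }
  res
}
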