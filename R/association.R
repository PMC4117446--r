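#' Residualize a vector on covariates
#'
#' Removes the least-squares projection of `values` onto an intercept plus
#' the covariate columns; the result is orthogonal to the intercept and to
#' every covariate column. Used to turn the N-times-squared-correlation
#' score test into a partial-correlation test when ancestry principal
#' components are included.
#'
#' @param values Numeric vector.
#' @param covariates Numeric matrix (or `NULL`/zero columns: mean-centring
#'   only). Must have full column rank once the intercept is added.
#' @return Numeric residual vector of the same length.
#' @export
residualize <- function(values, covariates = NULL) {
  n <- length(values)
  if (is.null(covariates) || NCOL(covariates) == 0L || length(covariates) == 0L)
    return(values - mean(values))
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != n)
    stop("covariate rows (", nrow(covariates), ") != length of values (", n, ")")
  X <- cbind(`(intercept)` = 1, covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_col <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("covariate matrix is rank deficient; collinear column(s): ",
         paste(drop_col, collapse = ", "))
  }
  qr.resid(qx, values)
}

# residualize every column of a matrix on the same covariates
.residualize_matrix <- function(M, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0L || length(covariates) == 0L)
    return(sweep(M, 2L, colMeans(M)))
  X <- cbind(1, as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("covariate matrix is rank deficient")
  qr.resid(qx, M)
}

# shared core of the informed/uninformed tests: correlation of residualized
# dosage columns with a residualized response, chisq = N * r^2
.score_scan <- function(dos_res, y_res, n_covar) {
  n <- nrow(dos_res)
  sxx <- colSums(dos_res^2)
  syy <- sum(y_res^2)
  sxy <- as.vector(crossprod(dos_res, y_res))
  ok <- sxx > .Machine$double.eps * n & syy > .Machine$double.eps * n
  r <- ifelse(ok, sxy / sqrt(sxx * syy), NA_real_)
  chisq <- n * r^2
  z <- sign(r) * sqrt(chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  beta <- ifelse(ok, sxy / sxx, NA_real_)
  df <- n - 2L - n_covar
  rss <- syy - beta^2 * sxx
  se <- ifelse(ok & df > 0, sqrt(pmax(rss, 0) / df / sxx), NA_real_)
  data.frame(n = n, r = r, chisq = chisq, z = z, p = p, beta = beta, se = se,
             flag = ifelse(ok, "ok", "unestimable"))
}

#' Association scan of a panel against an arbitrary response
#'
#' Tests every SNP in the panel against the response with the
#' N-times-squared-correlation score statistic: dosage and response are
#' residualized on the covariates, \eqn{r} is the Pearson correlation of
#' the residuals, \eqn{\chi^2 = N r^2} is referred to a 1-df chi-square,
#' and the effect size is the least-squares slope of the residualized
#' response on the residualized dosage. With a posterior-liability response
#' this is the age-at-onset informed test; with 0/1 status it is the
#' uninformed (standard) test.
#'
#' @param panel A [genotype_panel()].
#' @param response Numeric response vector aligned to the panel's rows.
#' @param covariates Optional covariate matrix (samples x covariates).
#' @param status Optional 0/1 vector used to report `n_cases`.
#' @return A `data.frame` (one row per SNP) with columns `snp`, `chr`,
#'   `pos`, `ea`, `oa`, `eaf`, `info`, `n`, `n_cases`, `r`, `chisq`, `z`,
#'   `p`, `beta`, `se`, `flag`.
#' @export
assoc_scan <- function(panel, response, covariates = NULL, status = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  n <- nrow(panel$dosage)
  if (length(response) != n)
    stop("response length (", length(response), ") != panel samples (", n, ")")
  dos_res <- .residualize_matrix(panel$dosage, covariates)
  y_res <- residualize(response, covariates)
  stats <- .score_scan(dos_res, y_res,
                       n_covar = if (is.null(covariates)) 0L else NCOL(covariates))
  out <- cbind(
    data.frame(snp = panel$snps$snp, chr = panel$snps$chr,
               pos = panel$snps$pos, ea = panel$snps$a1, oa = panel$snps$a2,
               eaf = unname(panel_eaf(panel)), info = panel$snps$info),
    stats)
  out$n_cases <- if (is.null(status)) NA_integer_ else sum(status == 1L)
  out[, c("snp", "chr", "pos", "ea", "oa", "eaf", "info", "n", "n_cases",
          "r", "chisq", "z", "p", "beta", "se", "flag")]
}

#' Age-at-onset informed association test for a single SNP
#'
#' @param dosage Numeric vector of expected dosages.
#' @param liabilities Posterior mean liabilities from
#'   [assign_liabilities()].
#' @param covariates Optional covariate matrix.
#' @return One-row `data.frame` with `n`, `r`, `chisq`, `z`, `p`, `beta`,
#'   `se`, `flag`.
#' @examples
#' d <- c(0, 1, 2, 0, 1)
#' informed_test(d, 0.3 * d - 0.1)  # perfect correlation: chisq = N
#' @export
informed_test <- function(dosage, liabilities, covariates = NULL) {
  if (length(dosage) != length(liabilities))
    stop("dosage and liability vectors differ in length")
  dos_res <- .residualize_matrix(cbind(dosage), covariates)
  y_res <- residualize(liabilities, covariates)
  .score_scan(dos_res, y_res,
              n_covar = if (is.null(covariates)) 0L else NCOL(covariates))
}

#' Uninformed (standard case-control) association test
#'
#' Identical machinery to [informed_test()] with the 0/1 affection status
#' as the response, so the informed and uninformed tests differ only in the
#' response vector.
#'
#' @param dosage Numeric vector of expected dosages.
#' @param status 0/1 affection status vector.
#' @param covariates Optional covariate matrix.
#' @return One-row `data.frame` as in [informed_test()].
#' @export
uninformed_test <- function(dosage, status, covariates = NULL) {
  if (!all(status %in% c(0, 1))) stop("`status` must be coded 0/1")
  informed_test(dosage, as.numeric(status), covariates)
}

#' Logistic odds ratios by cumulative age-at-onset quantile
#'
#' Post-hoc characterisation of an associated SNP: for each ascending
#' onset-age cut point, cases with onset at or below the cut are combined
#' with all controls and an additive-dosage logistic regression is fitted
#' by iteratively reweighted least squares (converged when the deviance
#' change is below `1e-8`, at most 50 iterations). A stronger odds ratio in
#' the youngest stratum than in the all-ages stratum is the signature of an
#' age-at-onset effect.
#'
#' @param dosage Expected dosage vector.
#' @param status 0/1 status vector.
#' @param ages Age vector (onset age for cases; controls' entries unused).
#' @param quantile_cuts Ascending onset-age cut points; cases with
#'   `age <= cut` enter the stratum. Use `Inf` for the all-ages stratum.
#' @param covariates Optional covariate matrix (default none).
#' @return `data.frame` with one row per cut: `cut`, `n_cases`,
#'   `n_controls`, `or`, `ci_lo`, `ci_hi`, `p`, `flag` (`"ok"` or
#'   `"separation"`).
#' @export
logistic_or_by_quantile <- function(dosage, status, ages, quantile_cuts,
                                    covariates = NULL) {
  if (is.unsorted(quantile_cuts, strictly = TRUE))
    stop("`quantile_cuts` must be strictly ascending")
  res <- lapply(quantile_cuts, function(cut) {
    keep <- status == 0L | (status == 1L & ages <= cut)
    d <- dosage[keep]; y <- status[keep]
    cv <- if (is.null(covariates)) NULL else as.matrix(covariates)[keep, , drop = FALSE]
    if (!any(y == 1L) || !any(y == 0L))
      stop("stratum at cut ", cut, " lacks cases or controls")
    X <- if (is.null(cv)) data.frame(dosage = d)
         else data.frame(dosage = d, cv)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = X, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
    co <- summary(fit)$coefficients["dosage", ]
    sep <- !fit$converged || abs(co[1L]) > 15 ||
      any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
    data.frame(
      cut = cut, n_cases = sum(y == 1L), n_controls = sum(y == 0L),
      or = if (sep) NA_real_ else exp(co[1L]),
      ci_lo = if (sep) NA_real_ else exp(co[1L] - 1.96 * co[2L]),
      ci_hi = if (sep) NA_real_ else exp(co[1L] + 1.96 * co[2L]),
      p = if (sep) NA_real_ else unname(co[4L]),
      flag = if (sep) "separation" else "ok")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write association results to TSV
#'
#' @param assoc `data.frame` from [assoc_scan()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_assoc_tsv <- function(assoc, path) {
  data.table::fwrite(assoc, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read association results written by [write_assoc_tsv()]
#'
#' @param path TSV path.
#' @return `data.frame` of per-SNP statistics.
#' @export
read_assoc_tsv <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}
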