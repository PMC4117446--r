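#' Effective sample size of a case-control study
#'
#' \eqn{N_{eff} = 4 / (1/n_{cases} + 1/n_{controls})}, the sample size of a
#' balanced study with equivalent power; the default basis for
#' sample-size-weighted meta-analysis of case-control studies.
#'
#' @param n_cases,n_controls Case and control counts.
#' @return Numeric effective sample size.
#' @export
effective_n <- function(n_cases, n_controls) {
  4 / (1 / n_cases + 1 / n_controls)
}

#' Stouffer sample-size-weighted Z meta-analysis
#'
#' Combines per-study signed normal scores for one SNP:
#' \eqn{Z_{meta} = \sum_i w_i Z_i / \sqrt{\sum_i w_i^2}} with
#' \eqn{w_i = \sqrt{N_{eff,i}}} by default (the sample-size scheme used for
#' case-control studies), or \eqn{w_i = \sqrt{N_i}}. Study Z signs must
#' already refer to one harmonized effect allele.
#'
#' @param z Vector of per-study signed Z scores.
#' @param n Per-study total sample sizes.
#' @param n_cases,n_controls Per-study case/control counts (needed for the
#'   `"neff"` scheme).
#' @param weight_scheme `"neff"` (default) or `"n"`.
#' @return List with `z_meta`, `p` (two-sided), `weights`.
#' @examples
#' stouffer_meta(c(1.96, 1.96), n = c(100, 100),
#'               n_cases = c(50, 50), n_controls = c(50, 50))
#' @export
stouffer_meta <- function(z, n = NULL, n_cases = NULL, n_controls = NULL,
                          weight_scheme = c("neff", "n")) {
  weight_scheme <- match.arg(weight_scheme)
  k <- length(z)
  if (k < 1L) stop("at least one study is required")
  w <- switch(weight_scheme,
    neff = {
      if (is.null(n_cases) || is.null(n_controls))
        stop("`neff` weights need n_cases and n_controls")
      sqrt(effective_n(n_cases, n_controls))
    },
    n = {
      if (is.null(n)) stop("`n` weights need per-study sample sizes")
      sqrt(n)
    })
  z_meta <- sum(w * z) / sqrt(sum(w^2))
  list(z_meta = z_meta,
       p = 2 * stats::pnorm(-abs(z_meta)),
       weights = w)
}

#' Genomic-control inflation factor and correction
#'
#' \eqn{\lambda} is the median association chi-square divided by the median
#' of the 1-df chi-square distribution (0.4549); statistics are deflated by
#' \eqn{\max(\lambda, 1)} so that genomic control never inflates
#' well-calibrated statistics.
#'
#' @param chisq Vector of 1-df association chi-squares for one study.
#' @param floor_at_one Deflate only (`TRUE`, the METAL convention) or apply
#'   \eqn{\lambda} as computed.
#' @return List with `lambda` and `corrected` chi-squares.
#' @export
genomic_control <- function(chisq, floor_at_one = TRUE) {
  chisq <- chisq[is.finite(chisq)]
  if (!length(chisq)) stop("no finite chi-square values")
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  divisor <- if (floor_at_one) max(lambda, 1) else lambda
  list(lambda = lambda, corrected = chisq / divisor)
}

#' Cochran's Q heterogeneity statistic
#'
#' Inverse-variance-weighted sum of squared deviations of study effects
#' from the pooled effect; referred to a chi-square with `k - 1` degrees of
#' freedom.
#'
#' @param betas Per-study effect estimates.
#' @param ses Per-study standard errors.
#' @return List with `Q`, `df`, `p`.
#' @export
cochran_q <- function(betas, ses) {
  k <- length(betas)
  if (k != length(ses)) stop("betas and ses differ in length")
  if (k < 2L) stop("Cochran's Q needs at least two studies")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - pooled)^2)
  list(Q = Q, df = k - 1L,
       p = stats::pchisq(Q, df = k - 1L, lower.tail = FALSE))
}

#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' @inheritParams cochran_q
#' @return List with `beta` (pooled), `se`, `z`, `p` (two-sided).
#' @export
ivw_fixed_meta <- function(betas, ses) {
  if (length(betas) != length(ses)) stop("betas and ses differ in length")
  if (length(betas) < 1L) stop("at least one study is required")
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  beta <- sum(w * betas) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- beta / se
  list(beta = beta, se = se, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Han-Eskin random-effects meta-analysis (RE2)
#'
#' Likelihood-ratio test of a non-zero mean effect allowing between-study
#' variance \eqn{\tau^2 \ge 0}, for trans-ethnic replication where
#' heterogeneity across ancestries is expected. The alternative profiles
#' the likelihood over \eqn{(\mu, \tau^2)}; the null fixes
#' \eqn{\mu = 0, \tau^2 = 0}. The p-value uses the asymptotic null mixture
#' \eqn{\frac{1}{2}\chi^2_1 + \frac{1}{2}\chi^2_2}; small-study tabulated
#' corrections are not applied and the result is flagged accordingly.
#'
#' @inheritParams cochran_q
#' @return List with `stat` (LR statistic), `mu`, `tau2`, `p`,
#'   `small_sample_correction = FALSE`.
#' @export
re2_han_eskin <- function(betas, ses) {
  k <- length(betas)
  if (k < 2L) stop("random-effects meta-analysis needs at least two studies")
  if (k != length(ses)) stop("betas and ses differ in length")
  if (any(ses <= 0)) stop("standard errors must be positive")
  v <- ses^2
  loglik <- function(mu, tau2)
    sum(stats::dnorm(betas, mean = mu, sd = sqrt(v + tau2), log = TRUE))
  prof <- function(tau2) {
    w <- 1 / (v + tau2)
    loglik(sum(w * betas) / sum(w), tau2)
  }
  upper <- max(stats::var(betas) * 5, max(v) * 5, 1e-3)
  opt <- stats::optimize(prof, interval = c(0, upper), maximum = TRUE,
                         tol = 1e-10)
  # the boundary tau2 = 0 is a candidate the interior optimizer can miss
  tau2_hat <- if (prof(0) >= opt$objective) 0 else opt$maximum
  l1 <- prof(tau2_hat)
  w <- 1 / (v + tau2_hat)
  mu_hat <- sum(w * betas) / sum(w)
  stat <- max(0, 2 * (l1 - loglik(0, 0)))
  p <- 0.5 * stats::pchisq(stat, df = 1, lower.tail = FALSE) +
       0.5 * stats::pchisq(stat, df = 2, lower.tail = FALSE)
  list(stat = stat, mu = mu_hat, tau2 = tau2_hat, p = p,
       small_sample_correction = FALSE)
}

#' Fisher's method for combining independent p-values
#'
#' \eqn{X = -2 \sum_i \ln p_i} referred to a chi-square with \eqn{2k}
#' degrees of freedom; used to combine discovery and replication evidence.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Combined p-value.
#' @examples
#' fisher_combine(c(2.5e-7, 0.0048))  # combined discovery + replication
#' @export
fisher_combine <- function(p) {
  if (!length(p)) stop("no p-values supplied")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

# strand-ambiguous allele pair (A/T or C/G)
.is_ambiguous <- function(a1, a2) {
  pair <- paste(pmin(toupper(a1), toupper(a2)), pmax(toupper(a1), toupper(a2)))
  pair %in% c("A T", "C G")
}

#' Meta-analyse per-centre association scans
#'
#' Combines the per-centre results of [assoc_scan()] across studies for
#' every SNP: per-study genomic control (on each study's full chi-square
#' vector, deflation floored at \eqn{\lambda = 1}), allele harmonization to
#' the first study carrying each SNP (signs flipped when effect/other
#' alleles are swapped; strand-ambiguous A/T and C/G SNPs pass through with
#' a warning), Stouffer sample-size-weighted Z combination, case coverage
#' (fraction of all cases contributed by the studies containing the SNP),
#' and Cochran's Q on the per-study effect sizes.
#'
#' @param scans Named list of per-centre `data.frame`s from
#'   [assoc_scan()] (names are study ids).
#' @param weight_scheme `"neff"` or `"n"`, see [stouffer_meta()].
#' @param gc Apply per-study genomic control before combining? Default
#'   `TRUE`.
#' @param total_cases Denominator for case coverage; defaults to the sum of
#'   each study's `n_cases`.
#' @return A `data.frame` with one row per SNP: `snp`, `chr`, `pos`, `ea`,
#'   `oa`, `n_studies`, `n`, `n_cases`, `case_coverage`, `z_meta`,
#'   `p_meta`, `q_stat`, `q_p`, `direction`; per-study lambdas in
#'   `attr(, "lambda")`.
#' @export
meta_analyse <- function(scans, weight_scheme = c("neff", "n"), gc = TRUE,
                         total_cases = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  if (is.null(names(scans)) || any(!nzchar(names(scans))))
    names(scans) <- paste0("study", seq_along(scans))
  scans <- lapply(scans, function(s) s[s$flag == "ok" & is.finite(s$z), ,
                                       drop = FALSE])
  lambdas <- rep(NA_real_, length(scans))
  names(lambdas) <- names(scans)
  for (i in seq_along(scans)) {
    s <- scans[[i]]
    if (!nrow(s)) next
    if (gc) {
      gcres <- genomic_control(s$chisq)
      lambdas[i] <- gcres$lambda
      s$chisq <- gcres$corrected
      s$z <- sign(s$z) * sqrt(s$chisq)
      s$p <- stats::pchisq(s$chisq, df = 1, lower.tail = FALSE)
    } else {
      lambdas[i] <- genomic_control(s$chisq)$lambda
    }
    scans[[i]] <- s
  }
  if (is.null(total_cases))
    total_cases <- sum(vapply(scans, function(s)
      if (nrow(s)) s$n_cases[1L] else 0L, numeric(1)), na.rm = TRUE)

  study_ids <- names(scans)
  long <- do.call(rbind, lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    if (!nrow(s)) return(NULL)
    cbind(s, study = i)
  }))
  if (is.null(long) || !nrow(long)) stop("no estimable SNPs in any study")
  # harmonize alleles to the first study carrying each SNP
  first <- !duplicated(long$snp)
  ref <- long[first, c("snp", "chr", "pos", "ea", "oa")]
  ri <- match(long$snp, ref$snp)
  same <- toupper(long$ea) == toupper(ref$ea[ri]) &
          toupper(long$oa) == toupper(ref$oa[ri])
  flipped <- toupper(long$ea) == toupper(ref$oa[ri]) &
             toupper(long$oa) == toupper(ref$ea[ri])
  if (any(!same & !flipped))
    stop("conflicting alleles across studies for SNP ",
         long$snp[which(!same & !flipped)[1L]])
  long$z[flipped] <- -long$z[flipped]
  long$beta[flipped] <- -long$beta[flipped]
  amb <- ref$snp[.is_ambiguous(ref$ea, ref$oa)]
  if (length(amb))
    warning("strand-ambiguous A/T or C/G SNPs passed through unflipped: ",
            paste(utils::head(amb, 5L), collapse = ", "),
            if (length(amb) > 5L) ", ...")

  w <- switch(weight_scheme,
              neff = sqrt(effective_n(long$n_cases, long$n - long$n_cases)),
              n = sqrt(long$n))
  g <- ri  # group index per long row
  nsnp <- nrow(ref)
  sum_wz <- rowsum(w * long$z, g)[, 1L]
  sum_w2 <- rowsum(w^2, g)[, 1L]
  z_meta <- sum_wz / sqrt(sum_w2)
  n_studies <- tabulate(g, nsnp)
  n_tot <- rowsum(long$n, g)[, 1L]
  ncas_tot <- rowsum(long$n_cases, g)[, 1L]
  # Cochran's Q over studies with finite (beta, se)
  okq <- is.finite(long$beta) & is.finite(long$se) & long$se > 0
  wq <- ifelse(okq, 1 / long$se^2, 0)
  kq <- rowsum(as.numeric(okq), g)[, 1L]
  sw <- rowsum(wq, g)[, 1L]
  swb <- rowsum(wq * long$beta, g)[, 1L]
  swb2 <- rowsum(wq * long$beta^2, g)[, 1L]
  Q <- pmax(swb2 - swb^2 / ifelse(sw > 0, sw, NA_real_), 0)
  Q[kq < 2L] <- NA_real_
  q_p <- stats::pchisq(Q, df = pmax(kq - 1L, 1L), lower.tail = FALSE)
  # METAL-style direction string (one character per study, ? when absent)
  dir_mat <- matrix("?", nrow = nsnp, ncol = length(study_ids))
  dir_mat[cbind(g, long$study)] <-
    ifelse(long$z > 0, "+", ifelse(long$z < 0, "-", "0"))
  out <- data.frame(
    snp = ref$snp, chr = ref$chr, pos = ref$pos, ea = ref$ea, oa = ref$oa,
    n_studies = n_studies, n = n_tot, n_cases = ncas_tot,
    case_coverage = if (total_cases > 0) ncas_tot / total_cases else NA_real_,
    z_meta = z_meta, p_meta = 2 * stats::pnorm(-abs(z_meta)),
    q_stat = unname(Q), q_p = unname(q_p),
    direction = apply(dir_mat, 1L, paste, collapse = ""),
    row.names = NULL)
  attr(out, "lambda") <- lambdas
  out
}

#' Case-coverage and heterogeneity filters for meta-analysed SNPs
#'
#' Retains SNPs present in studies contributing at least
#' `min_case_coverage` of all cases and with no evidence of between-study
#' heterogeneity (Cochran's Q p strictly greater than `min_q_p`). The
#' boundary conventions: coverage exactly at the threshold is kept; a Q
#' p-value exactly at the threshold is dropped. SNPs with undefined Q
#' (single study) pass the heterogeneity rule. Per-rule drop counts are
#' attached as attribute `filter_counts`.
#'
#' @param meta `data.frame` from [meta_analyse()].
#' @param min_case_coverage Minimum fraction of all cases, default 0.75.
#' @param min_q_p Heterogeneity threshold, default 0.001 (strict `>`).
#' @param verbose Emit a message with drop counts? Default `TRUE`.
#' @return The filtered `data.frame`.
#' @export
apply_meta_filters <- function(meta, min_case_coverage = 0.75,
                               min_q_p = 0.001, verbose = TRUE) {
  low_cov <- meta$case_coverage < min_case_coverage
  het <- !is.na(meta$q_p) & meta$q_p <= min_q_p
  keep <- !low_cov & !het
  if (verbose)
    message(sprintf(
      "apply_meta_filters: %d SNPs in, %d dropped (coverage<%g: %d, Q p<=%g: %d), %d retained",
      nrow(meta), sum(!keep), min_case_coverage, sum(low_cov), min_q_p,
      sum(het), sum(keep)))
  out <- meta[keep, , drop = FALSE]
  attr(out, "filter_counts") <- c(n_in = nrow(meta), n_coverage = sum(low_cov),
                                  n_het = sum(het), n_out = sum(keep))
  attr(out, "lambda") <- attr(meta, "lambda")
  out
}

#' Write meta-analysis results to TSV
#'
#' @param meta `data.frame` from [meta_analyse()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_meta_tsv <- function(meta, path) {
  data.table::fwrite(meta, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
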