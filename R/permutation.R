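#' Greedy LD clumping of association results
#'
#' Reduces an association scan to near-independent index SNPs: the
#' lowest-p unclaimed SNP is taken as an index, every SNP on the same
#' chromosome within `window` base pairs whose dosage-based \eqn{r^2} with
#' the index is at least `r2_max` is removed, and the procedure repeats.
#' Ties on p are broken by chromosome, position, then identifier, so the
#' retained set does not depend on input row order. \eqn{r^2} is the
#' squared Pearson correlation of expected dosages (composite LD; phase is
#' unavailable from dosages).
#'
#' @param assoc `data.frame` with columns `snp`, `chr`, `pos`, `p`.
#' @param dosage Numeric matrix of reference dosages (samples x SNPs),
#'   column names covering every `assoc$snp`.
#' @param window Clump window in base pairs, default 300000.
#' @param r2_max Removal threshold on \eqn{r^2}, default 0.25.
#' @return Character vector of retained SNP ids, in index (ascending p)
#'   order.
#' @export
ld_clump <- function(assoc, dosage, window = 3e5, r2_max = 0.25) {
  stopifnot(window > 0, r2_max > 0, r2_max < 1)
  missing_snp <- setdiff(assoc$snp, colnames(dosage))
  if (length(missing_snp))
    stop("SNP(s) missing from genotype panel: ",
         paste(utils::head(missing_snp, 5L), collapse = ", "))
  ord <- order(assoc$p, assoc$chr, assoc$pos, assoc$snp)
  a <- assoc[ord, , drop = FALSE]
  alive <- rep(TRUE, nrow(a))
  keep <- character(0)
  dm <- dosage[, a$snp, drop = FALSE]
  for (i in seq_len(nrow(a))) {
    if (!alive[i]) next
    keep <- c(keep, a$snp[i])
    alive[i] <- FALSE
    cand <- which(alive & a$chr == a$chr[i] & abs(a$pos - a$pos[i]) <= window)
    if (!length(cand)) next
    r <- suppressWarnings(stats::cor(dm[, i], dm[, cand, drop = FALSE]))
    r2 <- as.vector(r)^2
    r2[is.na(r2)] <- 0
    alive[cand[r2 >= r2_max]] <- FALSE
  }
  keep
}

# deterministic substream seed for one (perm_index, stratum); strata are
# hashed by name so results do not depend on stratum iteration order
.substream_seed <- function(seed, perm_index, stratum) {
  h <- sum(utf8ToInt(stratum) * seq_along(utf8ToInt(stratum)))
  as.integer((as.double(seed) * 48271 + perm_index * 69621 + h * 16807) %%
               2147483647)
}

# run fn() under a local RNG seeded with `seed`, restoring the caller's stream
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  fn()
}

#' Permute case ages-at-onset within centre and subtype
#'
#' Shuffles the onset ages of cases within each centre-by-subtype stratum;
#' controls are untouched and the multiset of ages per stratum is
#' preserved. Each (stratum, permutation index) pair uses an independent
#' substream derived from the master seed, so a given permutation is
#' reproducible regardless of evaluation order.
#'
#' @param ph Phenotype data.frame.
#' @param seed Master seed.
#' @param perm_index Permutation number (1-based).
#' @return The phenotype data.frame with case ages permuted.
#' @export
permute_ages <- function(ph, seed, perm_index) {
  ph <- validate_phenotype_table(ph)
  case_idx <- which(ph$status == 1L)
  strata <- split(case_idx,
                  paste(ph$centre[case_idx], ph$subtype[case_idx], sep = "\r"))
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    if (length(idx) < 2L) next
    s <- .substream_seed(seed, perm_index, nm)
    perm <- .with_seed(s, function() sample(length(idx)))
    ph$age[idx] <- ph$age[idx][perm]
  }
  ph
}

#' Empirical p-value from a permutation distribution
#'
#' \eqn{p = r/n} where `r` counts permutations strictly more extreme than
#' the observed statistic in the stated direction ("greater significance"
#' is a strict inequality; ties are counted separately). When `r = 0` the
#' value 0 is reported with a `"<1/n"` annotation.
#'
#' @param observed Observed statistic.
#' @param permuted Vector of permuted statistics.
#' @param direction `"greater"` if larger values are more extreme (e.g.
#'   sumZ), `"less"` if smaller values are (e.g. p-values).
#' @return List with `p`, `n_perm`, `n_extreme`, `n_ties`, `annotation`
#'   (`"<1/n"` when no permutation is more extreme, otherwise `""`).
#' @export
empirical_p <- function(observed, permuted, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  permuted <- permuted[is.finite(permuted)]
  n <- length(permuted)
  if (n < 1L) stop("at least one permutation is required")
  r <- if (direction == "greater") sum(permuted > observed)
       else sum(permuted < observed)
  ties <- sum(permuted == observed)
  list(p = r / n, n_perm = n, n_extreme = r, n_ties = ties,
       annotation = if (r == 0L) sprintf("<%g", 1 / n) else "")
}

# |Z| score of a two-sided p-value; computed from the upper tail directly so
# genome-wide-significant p-values keep full precision
.abs_z <- function(p) stats::qnorm(p / 2, lower.tail = FALSE)

#' Genome-wide summed-|Z| evaluation of the age-informed analysis
#'
#' For each p-value selection threshold, the SNP set is frozen from the
#' observed analysis (clumped SNPs with observed meta p below the
#' threshold); each SNP p-value is converted to \eqn{|Z| =
#' \Phi^{-1}(1-p/2)} and summed over the set (sumZ). The observed sumZ is
#' compared with the sumZ of every age-permuted re-analysis over the same
#' SNP set, giving an empirical p-value for a genome-wide age-at-onset
#' effect, alongside the median and IQR of the per-permutation proportion
#' of SNPs more significant in the observed analysis.
#'
#' @param observed_p Named vector of observed age-informed meta-analysis
#'   p-values (names are SNP ids; typically already LD-clumped).
#' @param perm_p Matrix of permuted meta p-values, permutations in rows,
#'   columns named by SNP id.
#' @param thresholds Descending p-value selection thresholds; default
#'   `c(0.05, 0.005, 0.0005, 0.00005)`.
#' @param selection_p Named p-value vector the thresholds are applied to.
#'   Defaults to `observed_p`; pass the case-control (uninformed) meta
#'   p-values to reproduce the design in which SNP sets are selected by a
#'   statistic that is invariant under age permutation (required for the
#'   empirical p to be well calibrated under the no-age-effect null).
#' @return `data.frame` with one row per threshold: `threshold`, `n_snps`,
#'   `sumz_obs`, `p_emp`, `annotation`, `prop_median`, `prop_q1`,
#'   `prop_q3`.
#' @export
sumz_evaluation <- function(observed_p, perm_p,
                            thresholds = c(0.05, 0.005, 0.0005, 0.00005),
                            selection_p = observed_p) {
  if (is.unsorted(rev(thresholds), strictly = TRUE))
    stop("`thresholds` must be strictly descending")
  if (is.null(names(observed_p)) || is.null(colnames(perm_p)))
    stop("observed p-values and permutation columns must be named by SNP")
  if (!all(names(observed_p) %in% colnames(perm_p)))
    stop("permutation matrix lacks columns for some observed SNPs")
  if (is.null(names(selection_p)))
    stop("`selection_p` must be named by SNP")
  rows <- lapply(thresholds, function(thr) {
    sel <- intersect(names(selection_p)[selection_p < thr],
                     names(observed_p))
    if (!length(sel))
      return(data.frame(threshold = thr, n_snps = 0L, sumz_obs = 0,
                        p_emp = NA_real_, annotation = "no SNPs selected",
                        prop_median = NA_real_, prop_q1 = NA_real_,
                        prop_q3 = NA_real_))
    sumz_obs <- sum(.abs_z(observed_p[sel]))
    pm <- perm_p[, sel, drop = FALSE]
    sumz_perm <- rowSums(.abs_z(pm))
    ep <- empirical_p(sumz_obs, sumz_perm, direction = "greater")
    props <- proportion_more_significant(observed_p[sel], pm)
    data.frame(threshold = thr, n_snps = length(sel), sumz_obs = sumz_obs,
               p_emp = ep$p, annotation = ep$annotation,
               prop_median = props$median, prop_q1 = props$q1,
               prop_q3 = props$q3)
  })
  do.call(rbind, rows)
}

#' Proportion of SNPs more significant in the observed analysis
#'
#' For each permutation, the fraction of the selected SNPs whose observed
#' p-value is strictly smaller than that permutation's p-value for the
#' same SNP; summarised by the median and interquartile range across
#' permutations. Values near 0.5 indicate no age-at-onset effect.
#'
#' @param observed_p Named vector of observed p-values for the selected
#'   SNPs.
#' @param perm_p Matrix of permuted p-values (permutations x SNPs) with
#'   matching column names.
#' @return List with `median`, `q1`, `q3`, and the per-permutation
#'   `proportions`.
#' @export
proportion_more_significant <- function(observed_p, perm_p) {
  perm_p <- perm_p[, names(observed_p), drop = FALSE]
  props <- rowMeans(sweep(perm_p, 2L, observed_p, ">"))
  qs <- stats::quantile(props, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = qs[2L], q1 = qs[1L], q3 = qs[3L], proportions = props)
}

#' Empirical age-at-onset effect p-value at a focal SNP
#'
#' The per-SNP analogue of the genome-wide evaluation: the proportion of
#' permutations showing stronger association (strictly smaller meta
#' p-value) than the observed age-informed analysis.
#'
#' @param observed_p Observed meta p-value of the focal SNP.
#' @param perm_p Vector of permuted meta p-values for that SNP.
#' @return As [empirical_p()] with `direction = "less"`.
#' @export
known_locus_age_effect <- function(observed_p, perm_p) {
  empirical_p(observed_p, perm_p, direction = "less")
}

#' Informed association + meta-analysis for a set of panels
#'
#' Convenience wrapper running the age-at-onset informed test in every
#' centre and Stouffer-combining the results; the workhorse behind the
#' permutation evaluation.
#'
#' @param panels Named list of [genotype_panel()]s (one per centre).
#' @param ph Phenotype data.frame covering all samples (matched to each
#'   panel by `sample_id` via the dosage row names).
#' @param model A [prevalence_model()].
#' @param phenotype Analysed phenotype, `"IS"` or a subtype.
#' @param covariates Optional named list of per-centre covariate matrices.
#' @param snps Optional character vector restricting the scan to these
#'   SNPs.
#' @param gc Apply genomic control in the meta step (default `FALSE`:
#'   evaluation SNP sets are small and a median-based lambda would be
#'   noise).
#' @param ... Passed to [meta_analyse()].
#' @return `data.frame` from [meta_analyse()].
#' @export
informed_meta_scan <- function(panels, ph, model, phenotype = "IS",
                               covariates = NULL, snps = NULL, gc = FALSE,
                               ...) {
  ph_sel <- select_phenotype(ph, phenotype)
  liab <- assign_liabilities(ph_sel, model, phenotype)
  .run_meta_scan(panels, ph_sel, liab, covariates, snps, gc, ...)
}

#' Uninformed (case-control) association + meta-analysis
#'
#' The unconditioned counterpart of [informed_meta_scan()]: the same
#' machinery with the 0/1 affection status as the response, for comparing
#' the age-informed and standard analyses.
#'
#' @inheritParams informed_meta_scan
#' @return `data.frame` from [meta_analyse()].
#' @export
uninformed_meta_scan <- function(panels, ph, model, phenotype = "IS",
                                 covariates = NULL, snps = NULL, gc = FALSE,
                                 ...) {
  ph_sel <- select_phenotype(ph, phenotype)
  y <- as.numeric(ph_sel$status)
  names(y) <- ph_sel$sample_id
  .run_meta_scan(panels, ph_sel, y, covariates, snps, gc, ...)
}

.run_meta_scan <- function(panels, ph_sel, response, covariates, snps, gc,
                           ...) {
  scans <- lapply(names(panels), function(cid) {
    panel <- panels[[cid]]
    if (!is.null(snps)) {
      keep <- panel$snps$snp %in% snps
      panel <- genotype_panel(panel$snps[keep, , drop = FALSE],
                              panel$dosage[, keep, drop = FALSE], cid)
    }
    ids <- rownames(panel$dosage)
    m <- match(ids, ph_sel$sample_id)
    ok <- !is.na(m)
    panel <- genotype_panel(panel$snps, panel$dosage[ok, , drop = FALSE], cid)
    cv <- if (is.null(covariates)) NULL else covariates[[cid]][ok, , drop = FALSE]
    assoc_scan(panel, response[m[ok]], covariates = cv,
               status = ph_sel$status[m[ok]])
  })
  names(scans) <- names(panels)
  meta_analyse(scans, gc = gc, ...)
}

#' Permutation distribution of informed meta p-values
#'
#' Runs [informed_meta_scan()] on `n_perm` within-centre, within-subtype
#' age permutations of the phenotype table and collects the meta p-value
#' of every SNP under each permutation.
#'
#' @inheritParams informed_meta_scan
#' @param n_perm Number of permutations (default 100; 1000 reproduces the
#'   full design).
#' @param seed Master seed for the permutation substreams.
#' @return Matrix of p-values, `n_perm` rows, columns named by SNP.
#' @export
permutation_pvalues <- function(panels, ph, model, phenotype = "IS",
                                snps = NULL, n_perm = 100, seed = 1,
                                covariates = NULL, gc = FALSE) {
  stopifnot(n_perm >= 1L)
  if (gc) {
    # genomic control re-estimates lambda per permutation: general path
    out <- NULL
    for (b in seq_len(n_perm)) {
      ph_b <- permute_ages(ph, seed = seed, perm_index = b)
      meta <- informed_meta_scan(panels, ph_b, model, phenotype,
                                 covariates = covariates, snps = snps, gc = TRUE)
      if (is.null(out))
        out <- matrix(NA_real_, nrow = n_perm, ncol = nrow(meta),
                      dimnames = list(NULL, meta$snp))
      out[b, meta$snp] <- meta$p_meta
    }
    return(out)
  }
  # fast path: dosages and covariates are fixed across permutations, so the
  # residualized dosage matrices and Stouffer weights are precomputed once;
  # each permutation only re-residualizes the liability response
  ph <- validate_phenotype_table(ph)
  ph_template <- select_phenotype(ph, phenotype)
  pre <- lapply(names(panels), function(cid) {
    panel <- panels[[cid]]
    if (!is.null(snps)) {
      keep <- panel$snps$snp %in% snps
      panel <- genotype_panel(panel$snps[keep, , drop = FALSE],
                              panel$dosage[, keep, drop = FALSE], cid)
    }
    m <- match(rownames(panel$dosage), ph_template$sample_id)
    ok <- !is.na(m)
    cv <- if (is.null(covariates)) NULL
          else covariates[[cid]][ok, , drop = FALSE]
    dos_res <- .residualize_matrix(panel$dosage[ok, , drop = FALSE], cv)
    status <- ph_template$status[m[ok]]
    list(snp = panel$snps$snp, dos_res = dos_res, sxx = colSums(dos_res^2),
         n = sum(ok), idx = m[ok], cv = cv,
         w = sqrt(effective_n(sum(status == 1L), sum(status == 0L))))
  })
  snp_union <- unique(unlist(lapply(pre, `[[`, "snp")))
  out <- matrix(NA_real_, nrow = n_perm, ncol = length(snp_union),
                dimnames = list(NULL, snp_union))
  ws <- vapply(pre, `[[`, numeric(1), "w")
  for (b in seq_len(n_perm)) {
    ph_b <- permute_ages(ph, seed = seed, perm_index = b)
    liab <- assign_liabilities(select_phenotype(ph_b, phenotype), model,
                               phenotype)
    zmat <- matrix(NA_real_, nrow = length(snp_union), ncol = length(pre),
                   dimnames = list(snp_union, NULL))
    for (i in seq_along(pre)) {
      p <- pre[[i]]
      y_res <- residualize(liab[p$idx], p$cv)
      sxy <- as.vector(crossprod(p$dos_res, y_res))
      r <- sxy / sqrt(p$sxx * sum(y_res^2))
      zmat[p$snp, i] <- sign(r) * sqrt(p$n * r^2)
    }
    wm <- matrix(ws, nrow = length(snp_union), ncol = length(pre),
                 byrow = TRUE)
    wm[is.na(zmat)] <- NA_real_
    z_meta <- rowSums(wm * zmat, na.rm = TRUE) /
      sqrt(rowSums(wm^2, na.rm = TRUE))
    out[b, ] <- 2 * stats::pnorm(-abs(z_meta))
  }
  out
}
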