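# shared fixture builders and independent oracles

# minimal panel with m SNPs and n samples; dosages drawn iid unless supplied
make_panel <- function(n = 50, m = 5, info = 1, dosage = NULL, seed = NULL,
                       chr = NULL, pos = NULL, centre_id = "c1",
                       maf = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dosage))
    dosage <- matrix(rbinom(n * m, 2L, maf), nrow = n)
  n <- nrow(dosage); m <- ncol(dosage)
  rownames(dosage) <- sprintf("s%04d", seq_len(n))
  snps <- data.frame(
    snp = sprintf("rs%03d", seq_len(m)),
    chr = if (is.null(chr)) rep(1L, m) else chr,
    pos = if (is.null(pos)) seq_len(m) * 100000L else pos,
    a1 = "A", a2 = "G",
    info = rep_len(info, m))
  colnames(dosage) <- snps$snp
  genotype_panel(snps, dosage, centre_id = centre_id)
}

# flat-prevalence model (constant K across ages)
flat_model <- function(K = 0.05, subtype_fraction = 0.20) {
  prevalence_model(c(40, 90), c(K, K), subtype_fraction = subtype_fraction)
}

make_phenotype <- function(n_cases, n_controls, centre = "c1",
                           case_ages = 65, control_ages = 70,
                           subtype = "LAA") {
  n <- n_cases + n_controls
  data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    centre = centre,
    status = rep(c(1L, 0L), c(n_cases, n_controls)),
    subtype = rep(c(subtype, "none"), c(n_cases, n_controls)),
    age = as.numeric(c(rep_len(case_ages, n_cases),
                       rep_len(control_ages, n_controls))))
}

# exhaustive reference implementation of greedy LD clumping, written as a
# direct transcription of the rule (recompute everything, no bookkeeping)
brute_force_clump <- function(assoc, dosage, window = 3e5, r2_max = 0.25) {
  remaining <- assoc[order(assoc$p, assoc$chr, assoc$pos, assoc$snp), ,
                     drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    index <- remaining[1L, ]
    kept <- c(kept, index$snp)
    drop <- logical(nrow(remaining))
    drop[1L] <- TRUE
    for (i in seq_len(nrow(remaining))[-1L]) {
      row <- remaining[i, ]
      if (row$chr == index$chr && abs(row$pos - index$pos) <= window) {
        r2 <- suppressWarnings(cor(dosage[, index$snp], dosage[, row$snp]))^2
        if (!is.na(r2) && r2 >= r2_max) drop[i] <- TRUE
      }
    }
    remaining <- remaining[!drop, , drop = FALSE]
  }
  kept
}

# per-centre informed and uninformed scans for a simulated cohort
cohort_scans <- function(cohort, phenotype = "IS") {
  ph <- select_phenotype(cohort$phenotype, phenotype)
  liab <- assign_liabilities(ph, cohort$model, phenotype)
  stat <- as.numeric(ph$status)
  res <- lapply(names(cohort$panels), function(cid) {
    p <- cohort$panels[[cid]]
    m <- match(rownames(p$dosage), ph$sample_id)
    ok <- !is.na(m)
    p <- genotype_panel(p$snps, p$dosage[ok, , drop = FALSE], cid)
    list(informed = assoc_scan(p, liab[m[ok]], status = stat[m[ok]]),
         uninformed = assoc_scan(p, stat[m[ok]], status = stat[m[ok]]))
  })
  names(res) <- names(cohort$panels)
  list(informed = lapply(res, `[[`, "informed"),
       uninformed = lapply(res, `[[`, "uninformed"))
}
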