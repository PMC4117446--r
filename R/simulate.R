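#' Simulation configuration for synthetic multi-centre cohorts
#'
#' Defines the generative model used for end-to-end validation: genotypes
#' at `m_snps` SNPs, a standard-normal liability with `n_causal` causal
#' SNPs of standardized effect `beta`, disease onset at the first age
#' (yearly grid) where the age-specific liability threshold drops below an
#' individual's liability, and case-control ascertainment at a uniformly
#' drawn exam age. Genetically loaded individuals therefore have earlier
#' onset, which is exactly the structure the age-at-onset informed
#' analysis exploits.
#'
#' @param seed Master seed.
#' @param n_centres Number of centres (studies).
#' @param n_cases,n_controls Per-centre case/control counts.
#' @param m_snps Total SNPs per panel.
#' @param n_causal Number of causal SNPs.
#' @param beta Standardized liability effect per causal SNP (scalar or
#'   length-`n_causal` vector); `sum(beta^2)` must stay below 1.
#' @param maf_range Allele-frequency range for simulated SNPs.
#' @param prevalence A [prevalence_model()]; defaults to
#'   [default_prevalence()].
#' @param phenotype Ascertained phenotype: `"IS"` uses the overall
#'   prevalence; a subtype label uses the subtype-scaled prevalence.
#' @param subtype_fractions Named probabilities used to label cases with
#'   subtypes when `phenotype = "IS"`.
#' @param exam_age_range Uniform range of exam ages (years).
#' @param dosage_noise Standard deviation of the imputation-noise signal;
#'   0 gives perfect dosages (info = 1).
#' @param freq_jitter_sd Per-centre jitter of allele frequencies on the
#'   logit scale (exercises between-study heterogeneity without
#'   confounding).
#' @param age_effect Coupling between liability and onset age in `[0, 1]`:
#'   1 (default) is the liability-threshold model; 0 makes onset
#'   independent of liability while preserving its marginal distribution
#'   (a generative null for the permutation evaluation).
#' @param ld_rho,ld_block_size Optional AR(1) haplotype correlation within
#'   blocks of non-causal SNPs (for clumping tests); `ld_rho = 0` disables.
#' @param max_draw_factor Abort ascertainment after
#'   `max_draw_factor * (n_cases + n_controls)` population draws per
#'   centre.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_centres = 2, n_cases = 1000,
                       n_controls = 1000, m_snps = 500, n_causal = 20,
                       beta = 0.12, maf_range = c(0.05, 0.5),
                       prevalence = default_prevalence(),
                       phenotype = "IS",
                       subtype_fractions = c(CE = 0.2, LAA = 0.2,
                                             SVD = 0.2, none = 0.4),
                       exam_age_range = c(40, 85), dosage_noise = 0.15,
                       freq_jitter_sd = 0.02, age_effect = 1,
                       ld_rho = 0, ld_block_size = 1,
                       max_draw_factor = 2000) {
  stopifnot(inherits(prevalence, "prevalence_model"),
            n_centres >= 1, n_cases >= 1, n_controls >= 1,
            m_snps >= 1, n_causal >= 0, n_causal <= m_snps,
            age_effect >= 0, age_effect <= 1,
            ld_rho >= 0, ld_rho < 1)
  beta <- if (n_causal == 0L) numeric(0) else rep_len(beta, n_causal)
  if (sum(beta^2) >= 1)
    stop("sum(beta^2) must be < 1 (residual liability variance must be positive)")
  structure(list(
    seed = seed, n_centres = n_centres, n_cases = n_cases,
    n_controls = n_controls, m_snps = m_snps, n_causal = n_causal,
    beta = beta, maf_range = maf_range, prevalence = prevalence,
    phenotype = phenotype, subtype_fractions = subtype_fractions,
    exam_age_range = exam_age_range, dosage_noise = dosage_noise,
    freq_jitter_sd = freq_jitter_sd, age_effect = age_effect,
    ld_rho = ld_rho, ld_block_size = ld_block_size,
    max_draw_factor = max_draw_factor), class = "sim_config")
}

# yearly age grid and (non-increasing) liability thresholds for the
# ascertained phenotype
.onset_grid <- function(config) {
  pm <- config$prevalence
  grid <- seq(min(pm$age), max(pm$age))
  t <- threshold_at_age(pm, grid, config$phenotype)
  if (is.unsorted(rev(t)))
    stop("prevalence must be non-decreasing in age to define onset by first threshold crossing")
  list(age = grid, t = t)
}

# onset age per individual: first grid age whose threshold is <= L, NA if none
.onset_age <- function(L, grid) {
  A <- length(grid$t)
  cnt <- findInterval(L, rev(grid$t))
  ifelse(cnt == 0L, NA_real_, grid$age[A + 1L - cnt])
}

# genotypes as two haplotypes with optional AR(1) latent correlation in blocks
.sim_genotypes <- function(n, p, rho = 0, block_size = 1) {
  m <- length(p)
  if (rho <= 0 || block_size <= 1L || m == 1L)
    return(matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), nrow = n))
  thr <- stats::qnorm(1 - p)
  hap <- function() {
    z <- matrix(stats::rnorm(n * m), nrow = n)
    for (j in 2L:m)
      if ((j - 1L) %% block_size != 0L)
        z[, j] <- rho * z[, j - 1L] + sqrt(1 - rho^2) * z[, j]
    sweep(z, 2L, thr, ">") + 0L
  }
  hap() + hap()
}

# one batch of the generative model: causal genotypes, liability, onset, exam
.sim_batch <- function(B, config, p_causal, grid) {
  nc <- config$n_causal
  if (nc > 0L) {
    g <- matrix(stats::rbinom(B * nc, 2L, rep(p_causal, each = B)), nrow = B)
    gs <- sweep(g, 2L, 2 * p_causal)
    gs <- sweep(gs, 2L, sqrt(2 * p_causal * (1 - p_causal)), "/")
    G <- as.vector(gs %*% config$beta)
  } else {
    g <- matrix(integer(0), nrow = B, ncol = 0L)
    G <- numeric(B)
  }
  L <- G + stats::rnorm(B, sd = sqrt(1 - sum(config$beta^2)))
  m <- config$age_effect
  L_onset <- if (m >= 1) L else m * L + sqrt(1 - m^2) * stats::rnorm(B)
  onset <- .onset_age(L_onset, grid)
  exam <- stats::runif(B, config$exam_age_range[1L], config$exam_age_range[2L])
  list(g = g, L = L, onset = onset, exam = exam,
       case = !is.na(onset) & onset <= exam)
}

#' Simulate an unascertained population
#'
#' Draws `n` individuals from the generative model without case-control
#' ascertainment; used to check that the simulated age-specific prevalence
#' matches the configured model.
#'
#' @param config A [sim_config()].
#' @param n Number of individuals.
#' @return `data.frame` with `liability`, `onset_age` (`NA` if never
#'   affected), `exam_age`, `status`; causal genotypes in
#'   `attr(, "genotypes")`.
#' @export
simulate_population <- function(config, n) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- .onset_grid(config)
  p_causal <- if (config$n_causal > 0L)
    stats::runif(config$n_causal, config$maf_range[1L], config$maf_range[2L])
  else numeric(0)
  b <- .sim_batch(n, config, p_causal, grid)
  out <- data.frame(liability = b$L, onset_age = b$onset, exam_age = b$exam,
                    status = as.integer(b$case))
  attr(out, "genotypes") <- b$g
  attr(out, "freq") <- p_causal
  out
}

#' Simulate a multi-centre case-control cohort
#'
#' Ascertains the configured numbers of cases and controls per centre by
#' rejection sampling from the age-structured liability-threshold model,
#' then attaches non-causal genotypes, imputation-like dosage noise, and
#' per-centre info scores. Cases record their onset age; controls their
#' exam age.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_cohort`: list with `phenotype`
#'   (combined phenotype table), `panels` (named list of
#'   [genotype_panel()]s with noisy dosages), `genotypes` (true genotype
#'   matrices), `liability` (true liabilities, named by sample), `truth`
#'   (causal SNP ids, effect sizes, config), and `model` (the prevalence
#'   model).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  grid <- .onset_grid(config)
  m <- config$m_snps
  p_base <- stats::runif(m, config$maf_range[1L], config$maf_range[2L])
  causal_idx <- if (config$n_causal > 0L) sort(sample.int(m, config$n_causal))
                else integer(0)
  snp_ids <- sprintf("snp%05d", seq_len(m))
  per_chr <- 250L
  snps0 <- data.frame(
    snp = snp_ids,
    chr = as.integer((seq_len(m) - 1L) %/% per_chr + 1L),
    pos = as.integer(((seq_len(m) - 1L) %% per_chr) * 50000L + 1L),
    a1 = "A", a2 = "G", info = NA_real_)

  centres <- sprintf("centre%02d", seq_len(config$n_centres))
  subs <- names(config$subtype_fractions)
  ph_list <- panels <- geno_list <- liab_list <- vector("list", length(centres))

  for (ci in seq_along(centres)) {
    cid <- centres[ci]
    p_c <- if (config$freq_jitter_sd > 0)
      stats::plogis(stats::qlogis(p_base) +
                      stats::rnorm(m, sd = config$freq_jitter_sd))
    else p_base
    p_c <- pmin(pmax(p_c, 1e-4), 1 - 1e-4)
    need_ca <- config$n_cases; need_co <- config$n_controls
    got_ca <- got_co <- 0L
    ca_g <- co_g <- list(); ca_onset <- co_exam <- ca_L <- co_L <- list()
    drawn <- 0L
    max_draw <- config$max_draw_factor * (need_ca + need_co)
    batch <- max(20000L, 2L * (need_ca + need_co))
    while (got_ca < need_ca || got_co < need_co) {
      if (drawn >= max_draw)
        stop("unattainable case/control counts in centre ", cid,
             " after ", drawn, " draws: prevalence too low for requested n")
      B <- min(batch, max_draw - drawn)
      b <- .sim_batch(B, config, p_c[causal_idx], grid)
      drawn <- drawn + B
      if (got_ca < need_ca && any(b$case)) {
        take <- utils::head(which(b$case), need_ca - got_ca)
        ca_g[[length(ca_g) + 1L]] <- b$g[take, , drop = FALSE]
        ca_onset[[length(ca_onset) + 1L]] <- b$onset[take]
        ca_L[[length(ca_L) + 1L]] <- b$L[take]
        got_ca <- got_ca + length(take)
      }
      if (got_co < need_co && any(!b$case)) {
        take <- utils::head(which(!b$case), need_co - got_co)
        co_g[[length(co_g) + 1L]] <- b$g[take, , drop = FALSE]
        co_exam[[length(co_exam) + 1L]] <- b$exam[take]
        co_L[[length(co_L) + 1L]] <- b$L[take]
        got_co <- got_co + length(take)
      }
    }
    n_c <- need_ca + need_co
    geno <- matrix(NA_integer_, nrow = n_c, ncol = m)
    if (config$n_causal > 0L)
      geno[, causal_idx] <- rbind(do.call(rbind, ca_g), do.call(rbind, co_g))
    null_idx <- setdiff(seq_len(m), causal_idx)
    if (length(null_idx))
      geno[, null_idx] <- .sim_genotypes(n_c, p_c[null_idx],
                                         rho = config$ld_rho,
                                         block_size = config$ld_block_size)
    ids <- sprintf("%s_%05d", cid, seq_len(n_c))
    rownames(geno) <- ids
    status <- rep(c(1L, 0L), c(need_ca, need_co))
    subtype <- rep("none", n_c)
    if (config$phenotype == "IS") {
      subtype[status == 1L] <- sample(subs, need_ca, replace = TRUE,
                                      prob = config$subtype_fractions)
    } else subtype[status == 1L] <- config$phenotype
    ph_list[[ci]] <- data.frame(
      sample_id = ids, centre = cid, status = status, subtype = subtype,
      age = round(c(unlist(ca_onset), unlist(co_exam)), 1))
    noisy <- add_dosage_noise(geno, config$dosage_noise)
    s_c <- snps0
    s_c$info <- noisy$info
    panels[[ci]] <- genotype_panel(s_c, noisy$dosage, centre_id = cid)
    geno_list[[ci]] <- geno
    liab_list[[ci]] <- stats::setNames(c(unlist(ca_L), unlist(co_L)), ids)
  }
  names(panels) <- names(geno_list) <- centres
  structure(list(
    phenotype = do.call(rbind, ph_list),
    panels = panels,
    genotypes = geno_list,
    liability = unlist(unname(liab_list)),
    model = config$prevalence,
    truth = list(causal = snp_ids[causal_idx], beta = config$beta,
                 freq = p_base[causal_idx], seed = config$seed,
                 phenotype = config$phenotype)),
    class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("sim_cohort: %d centres, %d samples, %d SNPs (%d causal)\n",
              length(x$panels), nrow(x$phenotype),
              ncol(x$panels[[1L]]$dosage), length(x$truth$causal)))
  invisible(x)
}

#' Add imputation-like noise to genotypes
#'
#' Emulates expected dosages from imputation with a linear-Bayes observer:
#' the true genotype is observed through additive noise and the expected
#' dosage is its posterior mean, \eqn{d = 2p + k(g - 2p) + k\eta} with
#' \eqn{k = var(g) / (var(g) + \sigma^2)} per SNP. Expected dosages
#' therefore shrink toward the allele-frequency mean and their variance is
#' `k * var(g)`, so the per-SNP info statistic
#' \eqn{var(d) / (2\,eaf(1-eaf))} decreases monotonically with the noise
#' level and equals 1 for noiseless polymorphic SNPs.
#'
#' @param genotypes Integer matrix of genotypes (samples x SNPs, values
#'   0/1/2).
#' @param noise_sd Noise standard deviation; 0 returns the genotypes
#'   unchanged.
#' @return List with `dosage` (clipped to `[0, 2]`) and `info` (clipped to
#'   `[0, 1]`; monomorphic SNPs get 0).
#' @export
add_dosage_noise <- function(genotypes, noise_sd = 0.15) {
  stopifnot(noise_sd >= 0)
  g <- as.matrix(genotypes)
  p <- colMeans(g) / 2
  varg <- 2 * p * (1 - p)
  mono <- varg <= 0
  if (noise_sd == 0) {
    dosage <- g
  } else {
    k <- ifelse(mono, 0, varg / (varg + noise_sd^2))
    eta <- matrix(stats::rnorm(length(g), sd = noise_sd), nrow = nrow(g))
    dosage <- sweep(sweep(g + eta, 2L, 2 * p), 2L, k, "*")
    dosage <- sweep(dosage, 2L, 2 * p, "+")
    dosage <- pmin(pmax(dosage, 0), 2)
  }
  if (noise_sd == 0) {
    # perfectly observed genotypes: info 1 by convention for polymorphic SNPs
    info <- ifelse(mono, 0, 1)
  } else {
    eaf <- colMeans(dosage) / 2
    denom <- 2 * eaf * (1 - eaf)
    info <- ifelse(denom > 0, apply(dosage, 2L, stats::var) / denom, 0)
    info <- pmin(pmax(info, 0), 1)
    info[mono] <- 0
  }
  dimnames(dosage) <- dimnames(g)
  list(dosage = dosage, info = unname(info))
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits `phenotype.tsv`, `prevalence.tsv`, one dosage file per centre
#' (`dosages_<centre>.tsv` or `.vcf` depending on dialect), and
#' `truth.json` holding the causal SNP ids, effect sizes and seed. Files
#' round-trip through the pipeline readers to within the 3-decimal dosage
#' quantization, and are byte-deterministic given the seed.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if missing).
#' @param dialect `"tsv"` or `"vcf"` dosage format.
#' @return Invisibly, the named vector of written paths.
#' @export
write_fixture_set <- function(cohort, dir, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(phenotype = file.path(dir, "phenotype.tsv"),
             prevalence = file.path(dir, "prevalence.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(cohort$phenotype, paths["phenotype"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_prevalence_table(cohort$model, paths["prevalence"])
  jsonlite::write_json(
    list(causal = cohort$truth$causal, beta = cohort$truth$beta,
         freq = cohort$truth$freq, seed = cohort$truth$seed,
         phenotype = cohort$truth$phenotype),
    paths["truth"], digits = NA, pretty = TRUE)
  for (cid in names(cohort$panels)) {
    f <- file.path(dir, sprintf("dosages_%s.%s", cid,
                                if (dialect == "tsv") "tsv" else "vcf"))
    if (dialect == "tsv") write_dosage_tsv(cohort$panels[[cid]], f)
    else write_dosage_vcf(cohort$panels[[cid]], f)
    paths[paste0("dosages_", cid)] <- f
  }
  invisible(paths)
}

#' Read a fixture set written by [write_fixture_set()]
#'
#' @param dir Directory containing the fixture files.
#' @param subtype_fraction Passed to [read_prevalence_table()].
#' @return List with `phenotype`, `panels`, `model`, `truth`.
#' @export
read_fixture_set <- function(dir, subtype_fraction = 0.20) {
  ph <- read_phenotype_table(file.path(dir, "phenotype.tsv"))
  model <- read_prevalence_table(file.path(dir, "prevalence.tsv"),
                                 subtype_fraction = subtype_fraction)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                            simplifyVector = TRUE)
           else NULL
  files <- list.files(dir, pattern = "^dosages_.*\\.(tsv|vcf)$",
                      full.names = TRUE)
  panels <- lapply(files, function(f) {
    cid <- sub("^dosages_(.*)\\.(tsv|vcf)$", "\\1", basename(f))
    if (grepl("\\.vcf$", f)) read_dosage_vcf(f, centre_id = cid)
    else read_dosage_tsv(f, centre_id = cid)
  })
  names(panels) <- sub("^dosages_(.*)\\.(tsv|vcf)$", "\\1", basename(files))
  list(phenotype = ph, panels = panels, model = model, truth = truth)
}
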