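#' Read a pipeline run configuration
#'
#' A single YAML file drives the discovery -> meta -> evaluation ->
#' combination flow. Recognised keys (all thresholds default to the
#' analysis design: info 0.3, MAF 0.01, case coverage 0.75, Q p > 0.001,
#' 300 kb / r2 0.25 clumping, 1000 permutations, selection thresholds
#' 0.05, 0.005, 0.0005, 0.00005):
#'
#' * `phenotype`: `IS`, `CE`, `LAA` or `SVD`
#' * `phenotype_file`, `prevalence_file`, `dosage_files` (named by centre)
#' * `subtype_fraction`
#' * `qc`: `min_info`, `min_maf`
#' * `meta`: `weight_scheme`, `genomic_control`, `min_case_coverage`,
#'   `min_q_p`
#' * `eval`: `window`, `r2_max`, `n_perm`, `thresholds`, `selection_p`
#' * `out_dir`, `seed`
#' * `simulate`: arguments passed to [sim_config()] for `cmd_simulate`
#'
#' @param path YAML file path.
#' @return A `run_config` list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    phenotype = "IS", subtype_fraction = 0.20,
    qc = list(min_info = 0.3, min_maf = 0.01),
    meta = list(weight_scheme = "neff", genomic_control = TRUE,
                min_case_coverage = 0.75, min_q_p = 0.001),
    eval = list(window = 3e5, r2_max = 0.25, n_perm = 1000,
                thresholds = c(0.05, 0.005, 0.0005, 0.00005),
                selection_p = 0.05),
    out_dir = "onsetGWAS_out", seed = 1)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
    else if (is.list(defaults[[k]]))
      for (kk in names(defaults[[k]]))
        if (is.null(cfg[[k]][[kk]])) cfg[[k]][[kk]] <- defaults[[k]][[kk]]
  }
  for (f in c("phenotype_file", "prevalence_file"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured file does not exist: ", cfg[[f]])
  for (f in unlist(cfg$dosage_files))
    if (!file.exists(f)) stop("configured dosage file does not exist: ", f)
  structure(cfg, class = "run_config")
}

# manifest with enough provenance to reproduce a run (no timestamps, so
# identical configs give byte-identical outputs)
.write_manifest <- function(cfg, stage, inputs, outputs, path) {
  man <- list(
    stage = stage,
    package = "onsetGWAS",
    version = as.character(utils::packageVersion("onsetGWAS")),
    seed = cfg$seed,
    phenotype = cfg$phenotype,
    inputs = {
      md5 <- tools::md5sum(inputs[file.exists(inputs)])
      names(md5) <- basename(names(md5))  # keep manifests path-independent
      as.list(md5)
    },
    outputs = basename(outputs))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.load_inputs <- function(cfg) {
  ph <- read_phenotype_table(cfg$phenotype_file)
  model <- read_prevalence_table(cfg$prevalence_file,
                                 subtype_fraction = cfg$subtype_fraction)
  panels <- lapply(names(cfg$dosage_files), function(cid) {
    f <- cfg$dosage_files[[cid]]
    if (grepl("\\.vcf(\\.gz)?$", f)) read_dosage_vcf(f, centre_id = cid)
    else read_dosage_tsv(f, centre_id = cid)
  })
  names(panels) <- names(cfg$dosage_files)
  list(ph = ph, model = model, panels = panels)
}

# per-centre covariates: PC columns of the phenotype table, aligned to the
# panel's samples
.centre_covariates <- function(ph, panel) {
  pcs <- pc_columns(ph)
  if (!length(pcs)) return(NULL)
  m <- match(rownames(panel$dosage), ph$sample_id)
  as.matrix(ph[m, pcs, drop = FALSE])
}

#' Pipeline stage: simulate a cohort and write fixture files
#'
#' @param cfg A `run_config` (its `simulate` block is passed to
#'   [sim_config()], with the config seed).
#' @param dialect Dosage output dialect, `"tsv"` or `"vcf"`.
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(cfg, dialect = "tsv") {
  sim_args <- cfg$simulate
  sim_args$seed <- cfg$seed
  sim_args$phenotype <- cfg$phenotype
  config <- do.call(sim_config, sim_args)
  cohort <- simulate_cohort(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture_set(cohort, cfg$out_dir, dialect = dialect)
  .write_manifest(cfg, "simulate", character(0), paths,
                  file.path(cfg$out_dir, "manifest_simulate.json"))
  invisible(paths)
}

#' Pipeline stage: per-centre association scans
#'
#' Runs QC and the age-at-onset informed (or uninformed) test in every
#' centre, writing one association TSV per centre.
#'
#' @param cfg A `run_config`.
#' @param informed Use posterior mean liabilities (`TRUE`, default) or the
#'   0/1 status (`FALSE`).
#' @return Invisibly, the written association file paths.
#' @export
cmd_assoc <- function(cfg, informed = TRUE) {
  inp <- .load_inputs(cfg)
  ph_sel <- select_phenotype(inp$ph, cfg$phenotype)
  liab <- if (informed)
    assign_liabilities(ph_sel, inp$model, cfg$phenotype) else NULL
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  for (cid in names(inp$panels)) {
    panel <- qc_filter(inp$panels[[cid]], cfg$qc$min_info, cfg$qc$min_maf)
    m <- match(rownames(panel$dosage), ph_sel$sample_id)
    ok <- !is.na(m)
    panel <- genotype_panel(panel$snps, panel$dosage[ok, , drop = FALSE], cid)
    cv <- .centre_covariates(ph_sel, panel)
    y <- if (informed) liab[m[ok]] else as.numeric(ph_sel$status[m[ok]])
    assoc <- assoc_scan(panel, y, covariates = cv,
                        status = ph_sel$status[m[ok]])
    f <- file.path(cfg$out_dir,
                   sprintf("assoc_%s_%s_%s.tsv", cfg$phenotype,
                           if (informed) "informed" else "uninformed", cid))
    write_assoc_tsv(assoc, f)
    outs <- c(outs, f)
  }
  .write_manifest(cfg, "assoc",
                  c(cfg$phenotype_file, cfg$prevalence_file,
                    unlist(cfg$dosage_files)), outs,
                  file.path(cfg$out_dir, "manifest_assoc.json"))
  invisible(outs)
}

#' Pipeline stage: meta-analysis across centres
#'
#' Reads the per-centre association TSVs written by [cmd_assoc()],
#' Stouffer-combines them with per-study genomic control, applies the
#' case-coverage and heterogeneity filters, and writes the meta TSV plus a
#' lambda report.
#'
#' @param cfg A `run_config`.
#' @param informed Which association run to combine.
#' @return Invisibly, the meta TSV path.
#' @export
cmd_meta <- function(cfg, informed = TRUE) {
  tag <- if (informed) "informed" else "uninformed"
  files <- list.files(cfg$out_dir, full.names = TRUE,
                      pattern = sprintf("^assoc_%s_%s_.*\\.tsv$",
                                        cfg$phenotype, tag))
  if (!length(files)) stop("no association files found; run cmd_assoc first")
  scans <- lapply(files, read_assoc_tsv)
  names(scans) <- sub(sprintf("^assoc_%s_%s_(.*)\\.tsv$", cfg$phenotype, tag),
                      "\\1", basename(files))
  meta <- meta_analyse(scans, weight_scheme = cfg$meta$weight_scheme,
                       gc = isTRUE(cfg$meta$genomic_control))
  filtered <- apply_meta_filters(meta, cfg$meta$min_case_coverage,
                                 cfg$meta$min_q_p)
  out <- file.path(cfg$out_dir, sprintf("meta_%s_%s.tsv", cfg$phenotype, tag))
  write_meta_tsv(filtered, out)
  lam <- file.path(cfg$out_dir, sprintf("lambda_%s_%s.json", cfg$phenotype, tag))
  jsonlite::write_json(as.list(attr(meta, "lambda")), lam, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  .write_manifest(cfg, "meta", files, c(out, lam),
                  file.path(cfg$out_dir, sprintf("manifest_meta_%s.json", tag)))
  invisible(out)
}

#' Pipeline stage: permutation evaluation of the age-informed analysis
#'
#' Reproduces the evaluation design: SNPs are selected and LD-clumped on
#' the *uninformed* (case-control) meta-analysis — a statistic invariant
#' under age permutation — then the observed age-informed meta-analysis at
#' those SNPs is compared with `eval$n_perm` within-centre age
#' permutations via the summed-|Z| statistic and the
#' proportion-more-significant summaries, written as a JSON report.
#'
#' @param cfg A `run_config`.
#' @param focal_snps Optional SNP ids for per-SNP age-effect empirical
#'   p-values.
#' @return Invisibly, the JSON report path.
#' @export
cmd_evaluate <- function(cfg, focal_snps = NULL) {
  inp <- .load_inputs(cfg)
  panels <- lapply(inp$panels, qc_filter, cfg$qc$min_info, cfg$qc$min_maf,
                   verbose = FALSE)
  meta <- uninformed_meta_scan(panels, inp$ph, inp$model, cfg$phenotype,
                               gc = isTRUE(cfg$meta$genomic_control))
  sel <- meta[meta$p_meta < cfg$eval$selection_p, , drop = FALSE]
  if (!nrow(sel)) stop("no SNPs pass the selection threshold")
  # LD reference: pooled dosages over SNPs present in every centre after QC
  common <- Reduce(intersect, lapply(panels, function(p) p$snps$snp))
  sel <- sel[sel$snp %in% common, , drop = FALSE]
  if (!nrow(sel)) stop("no selected SNP is present in every centre")
  pooled <- do.call(rbind, lapply(panels, function(p)
    p$dosage[, common, drop = FALSE]))
  assoc <- data.frame(snp = sel$snp, chr = sel$chr, pos = sel$pos,
                      p = sel$p_meta)
  clumped <- ld_clump(assoc, pooled, window = cfg$eval$window,
                      r2_max = cfg$eval$r2_max)
  sel_p <- stats::setNames(sel$p_meta, sel$snp)[clumped]
  obs_meta <- informed_meta_scan(panels, inp$ph, inp$model, cfg$phenotype,
                                 snps = clumped, gc = FALSE)
  obs_p <- stats::setNames(obs_meta$p_meta, obs_meta$snp)
  perm_p <- permutation_pvalues(panels, inp$ph, inp$model, cfg$phenotype,
                                snps = clumped, n_perm = cfg$eval$n_perm,
                                seed = cfg$seed)
  ev <- sumz_evaluation(obs_p, perm_p, thresholds = cfg$eval$thresholds,
                        selection_p = sel_p)
  report <- list(
    phenotype = cfg$phenotype, n_perm = cfg$eval$n_perm,
    n_selected = nrow(sel), n_clumped = length(clumped),
    thresholds = lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ])))
  if (!is.null(focal_snps)) {
    report$focal <- lapply(intersect(focal_snps, colnames(perm_p)), function(s)
      c(list(snp = s),
        known_locus_age_effect(obs_p[[s]], perm_p[, s])[c("p", "n_perm")]))
  }
  out <- file.path(cfg$out_dir, sprintf("evaluate_%s.json", cfg$phenotype))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  .write_manifest(cfg, "evaluate",
                  c(cfg$phenotype_file, cfg$prevalence_file,
                    unlist(cfg$dosage_files)), out,
                  file.path(cfg$out_dir, "manifest_evaluate.json"))
  invisible(out)
}

#' Pipeline stage: combine discovery and replication p-values
#'
#' Fisher's method over the supplied p-values; prints and returns the
#' combined p.
#'
#' @param p Vector of p-values (e.g. discovery and replication).
#' @param quiet Suppress printing.
#' @return The combined p-value.
#' @examples
#' cmd_combine(c(2.5e-7, 0.0048))
#' @export
cmd_combine <- function(p, quiet = FALSE) {
  comb <- fisher_combine(p)
  if (!quiet)
    cat(sprintf("Fisher's method: combined p = %.3g (from %s)\n", comb,
                paste(signif(p, 3), collapse = ", ")))
  invisible(comb)
}
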