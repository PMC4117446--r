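#' Read a phenotype table
#'
#' Reads the per-sample phenotype TSV used throughout the pipeline. Required
#' columns: `sample_id`, `centre`, `status` (0 = control, 1 = case),
#' `subtype` (one of `CE`, `LAA`, `SVD`, `IS`, `none`), and `age` (years:
#' age-at-onset for cases, age at exam/blood draw for controls; missing
#' encoded as `NA`). Any columns named `PC1`, `PC2`, ... are treated as
#' ancestry-informative principal-component covariates.
#'
#' @param path File path of the TSV (header required).
#' @return A `data.frame` with validated columns and an `age_missing` flag.
#' @export
read_phenotype_table <- function(path) {
  ph <- utils::read.delim(path, header = TRUE,
                          colClasses = c(sample_id = "character",
                                         centre = "character",
                                         subtype = "character"))
  validate_phenotype_table(ph)
}

#' Validate a phenotype data.frame
#'
#' @param ph A data.frame with the columns described in
#'   [read_phenotype_table()].
#' @return The validated data.frame, with `age_missing` added if absent.
#' @export
validate_phenotype_table <- function(ph) {
  need <- c("sample_id", "centre", "status", "subtype", "age")
  miss <- setdiff(need, names(ph))
  if (length(miss))
    stop("phenotype table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(ph) == 0L) stop("phenotype table is empty")
  if (anyDuplicated(ph$sample_id))
    stop("duplicated sample_id in phenotype table")
  if (!all(ph$status %in% c(0L, 1L)))
    stop("`status` must be coded 0 (control) / 1 (case)")
  ph$age <- as.numeric(ph$age)
  ph$age_missing <- is.na(ph$age)
  ph
}

# principal-component covariate columns, in numeric order
pc_columns <- function(ph) {
  pcs <- grep("^PC[0-9]+$", names(ph), value = TRUE)
  pcs[order(as.integer(sub("^PC", "", pcs)))]
}

#' Median-impute missing ages within centre and status
#'
#' Missing ages are replaced by the median age of non-missing samples in the
#' same centre and affection-status stratum; if a stratum has no observed
#' age at all, the global median over all samples of the same status is
#' used, then the overall global median.
#'
#' @param ph A validated phenotype data.frame.
#' @return The data.frame with `age` complete and `age_missing` marking the
#'   originally missing records.
#' @export
impute_missing_ages <- function(ph) {
  ph <- validate_phenotype_table(ph)
  if (!anyNA(ph$age)) return(ph)
  if (all(is.na(ph$age))) stop("all ages are missing: cannot impute")
  global_med <- stats::median(ph$age, na.rm = TRUE)
  status_med <- tapply(ph$age, ph$status, stats::median, na.rm = TRUE)
  key <- interaction(ph$centre, ph$status, drop = TRUE)
  strat_med <- tapply(ph$age, key, stats::median, na.rm = TRUE)
  idx <- which(is.na(ph$age))
  for (i in idx) {
    m <- strat_med[[as.character(key[i])]]
    if (is.na(m)) m <- status_med[[as.character(ph$status[i])]]
    if (is.na(m)) m <- global_med
    ph$age[i] <- m
  }
  ph
}

#' Restrict a phenotype table to one analysed phenotype
#'
#' For the overall phenotype (`"IS"`) all cases are retained; for a subtype
#' analysis only cases carrying that subtype label are retained. Controls
#' are always retained.
#'
#' @param ph A validated phenotype data.frame.
#' @param phenotype `"IS"` or a subtype label (`"CE"`, `"LAA"`, `"SVD"`).
#' @return The subset data.frame.
#' @export
select_phenotype <- function(ph, phenotype = "IS") {
  ph <- validate_phenotype_table(ph)
  if (identical(phenotype, "IS")) return(ph)
  keep <- ph$status == 0L | ph$subtype == phenotype
  out <- ph[keep, , drop = FALSE]
  if (!any(out$status == 1L))
    stop("no cases with subtype ", phenotype, " in phenotype table")
  out
}

#' Assign posterior mean liabilities to a cohort
#'
#' The core covariate-informed transformation: each case receives the
#' posterior mean of the liability truncated above the age-specific
#' threshold at its age-at-onset, \eqn{\phi(t(a))/K_{eff}(a)}; each control
#' receives the posterior mean of the lower (unaffected) tail at its exam
#' age, \eqn{-\phi(t(a))/(1-K_{eff}(a))}. Missing ages are median-imputed
#' within centre and status first. Setting `control_threshold = "pooled"`
#' conditions all controls on a single pooled prevalence instead of their
#' own exam age.
#'
#' @param ph Phenotype data.frame (will be validated; rows define the
#'   alignment of the returned vector).
#' @param model A [prevalence_model()].
#' @param phenotype `"IS"` or a subtype label; determines the effective
#'   prevalence via the subtype fraction.
#' @param control_threshold `"age"` (default: controls conditioned on their
#'   exam age) or `"pooled"`.
#' @param pooled_prevalence Prevalence used when
#'   `control_threshold = "pooled"`; defaults to the model prevalence at
#'   the mean control age.
#' @return Named numeric vector of posterior mean liabilities, one per row
#'   of `ph`, names taken from `sample_id`.
#' @examples
#' pm <- default_prevalence()
#' ph <- data.frame(sample_id = c("a", "b"), centre = "c1",
#'                  status = c(1L, 0L), subtype = c("LAA", "none"),
#'                  age = c(60, 70))
#' assign_liabilities(ph, pm, phenotype = "LAA")
#' @export
assign_liabilities <- function(ph, model, phenotype = "IS",
                               control_threshold = c("age", "pooled"),
                               pooled_prevalence = NULL) {
  control_threshold <- match.arg(control_threshold)
  stopifnot(inherits(model, "prevalence_model"))
  ph <- impute_missing_ages(ph)
  is_case <- ph$status == 1L
  liab <- numeric(nrow(ph))

  if (any(is_case)) {
    K <- prevalence_at(model, ph$age[is_case], phenotype)
    liab[is_case] <- posterior_mean_case(stats::qnorm(1 - K), K)
  }
  if (any(!is_case)) {
    if (control_threshold == "age") {
      K <- prevalence_at(model, ph$age[!is_case], phenotype)
    } else {
      K0 <- if (is.null(pooled_prevalence))
        prevalence_at(model, mean(ph$age[!is_case]), phenotype)
      else pooled_prevalence * .subtype_scale(model, phenotype)
      K <- rep(K0, sum(!is_case))
    }
    liab[!is_case] <- posterior_mean_control(stats::qnorm(1 - K), K)
  }
  names(liab) <- ph$sample_id
  liab
}
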