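#' Age-specific prevalence model
#'
#' Builds the prevalence model that underlies the liability-threshold
#' analysis: a strictly increasing age grid, the overall disease prevalence
#' \eqn{K(a)} at each grid age, and the fraction of overall prevalence
#' attributed to each aetiological subtype. Prevalence between grid ages is
#' interpolated piecewise-linearly; ages outside the grid are clamped to the
#' nearest grid end (thresholds are not extrapolated into sparse age tails).
#'
#' @param age Numeric vector of grid ages in years, strictly increasing.
#' @param prevalence Numeric vector of disease prevalences on `(0, 1)`,
#'   one per grid age.
#' @param subtype_fraction Fraction of overall prevalence attributed to a
#'   single subtype; scalar in `(0, 1]`. May also be a named vector with one
#'   entry per subtype label. Default 0.20, the approximate share of each
#'   major ischaemic-stroke subtype in population-based studies.
#' @return An object of class `prevalence_model`.
#' @examples
#' pm <- prevalence_model(c(45, 65, 85), c(0.001, 0.012, 0.05))
#' prevalence_at(pm, 70)
#' threshold_at_age(pm, 70, phenotype = "LAA")
#' @seealso [threshold_at_age()], [assign_liabilities()],
#'   [default_prevalence()]
#' @export
prevalence_model <- function(age, prevalence, subtype_fraction = 0.20) {
  if (length(age) < 1L || length(age) != length(prevalence))
    stop("`age` and `prevalence` must be non-empty and of equal length")
  if (anyNA(age) || anyNA(prevalence))
    stop("prevalence model must not contain missing values")
  if (length(age) > 1L && any(diff(age) <= 0))
    stop("`age` grid must be strictly increasing")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("every prevalence must lie strictly inside (0, 1)")
  if (any(subtype_fraction <= 0 | subtype_fraction > 1))
    stop("`subtype_fraction` must lie in (0, 1]")
  structure(
    list(age = as.numeric(age), prevalence = as.numeric(prevalence),
         subtype_fraction = subtype_fraction),
    class = "prevalence_model"
  )
}

#' @export
print.prevalence_model <- function(x, ...) {
  cat("Age-specific prevalence model\n")
  cat(sprintf("  age grid : %s years (%d points)\n",
              paste(range(x$age), collapse = "-"), length(x$age)))
  cat(sprintf("  K(a)     : %.4g at %g y to %.4g at %g y\n",
              x$prevalence[1L], x$age[1L],
              x$prevalence[length(x$age)], x$age[length(x$age)]))
  cat(sprintf("  subtype fraction: %s\n",
              paste(signif(x$subtype_fraction, 3), collapse = ", ")))
  invisible(x)
}

#' Default ischaemic-stroke prevalence table
#'
#' A documented default prevalence-by-age table consistent with stroke
#' epidemiology: prevalence rises from roughly 0.1% at age 45 to about 5%
#' at age 85. Intended for simulation and examples; real analyses should
#' supply a study-specific table via [read_prevalence_table()].
#'
#' @param subtype_fraction Passed to [prevalence_model()].
#' @return A `prevalence_model`.
#' @export
default_prevalence <- function(subtype_fraction = 0.20) {
  prevalence_model(
    age        = c(45, 55, 65, 75, 85),
    prevalence = c(0.001, 0.004, 0.012, 0.028, 0.050),
    subtype_fraction = subtype_fraction
  )
}

.subtype_labels <- c("CE", "LAA", "SVD")

# effective prevalence for the analysed phenotype; subtypes scale the overall
# K(a) by the configured fraction, constant across age
.subtype_scale <- function(model, phenotype) {
  if (identical(phenotype, "IS")) return(1)
  sf <- model$subtype_fraction
  if (!is.null(names(sf)) && phenotype %in% names(sf)) return(unname(sf[phenotype]))
  sf[1L]
}

#' Interpolated prevalence at given ages
#'
#' @param model A [prevalence_model()].
#' @param age Numeric vector of ages (years); ages outside the grid are
#'   clamped to the nearest grid end.
#' @param phenotype `"IS"` for the overall phenotype, or a subtype label,
#'   in which case the overall prevalence is scaled by the subtype fraction.
#' @return Numeric vector of effective prevalences \eqn{K_{eff}(a)}.
#' @export
prevalence_at <- function(model, age, phenotype = "IS") {
  stopifnot(inherits(model, "prevalence_model"))
  if (any(!is.finite(age))) stop("`age` must be finite")
  k <- if (length(model$age) == 1L) rep(model$prevalence, length(age))
       else stats::approx(model$age, model$prevalence, xout = age, rule = 2)$y
  k <- k * .subtype_scale(model, phenotype)
  if (any(k <= 0 | k >= 1))
    stop("effective prevalence outside (0, 1): invalid model")
  k
}

#' Liability threshold at a given age
#'
#' Converts effective age-specific prevalence into the liability-threshold
#' scale: \eqn{t(a) = \Phi^{-1}(1 - K_{eff}(a))}, so that the proportion of
#' the standard-normal liability distribution above the threshold equals the
#' disease prevalence at that age.
#'
#' @inheritParams prevalence_at
#' @return Numeric vector of thresholds (standard-normal liability units).
#' @export
threshold_at_age <- function(model, age, phenotype = "IS") {
  stats::qnorm(1 - prevalence_at(model, age, phenotype))
}

.check_tk <- function(t, K, tol = 1e-6) {
  if (any(K <= 0 | K >= 1)) stop("prevalence must lie strictly inside (0, 1)")
  if (any(abs(stats::qnorm(1 - K) - t) > tol))
    stop("inconsistent (threshold, prevalence) pair: t must equal qnorm(1 - K)")
}

#' Posterior mean liability of a case
#'
#' Mean of the standard normal truncated above the threshold,
#' \eqn{E[L \mid L > t] = \phi(t) / K}: the expected liability of an
#' affected individual whose disease prevalence at onset age is `K`.
#'
#' @param t Liability threshold(s), `qnorm(1 - K)`.
#' @param K Disease prevalence(s) in `(0, 1)` matching `t`.
#' @return Numeric vector of posterior mean liabilities (always `> t`).
#' @examples
#' posterior_mean_case(0, 0.5)              # 0.7979
#' posterior_mean_case(qnorm(0.99), 0.01)   # 2.6652
#' @export
posterior_mean_case <- function(t, K) {
  .check_tk(t, K)
  stats::dnorm(t) / K
}

#' Posterior mean liability of a control
#'
#' Mean of the standard normal truncated below the threshold,
#' \eqn{E[L \mid L \le t] = -\phi(t) / (1 - K)}: the expected liability of
#' an unaffected individual given the prevalence at their exam age.
#'
#' @inheritParams posterior_mean_case
#' @return Numeric vector of posterior mean liabilities (always `< t`).
#' @export
posterior_mean_control <- function(t, K) {
  .check_tk(t, K)
  -stats::dnorm(t) / (1 - K)
}

#' Read a two-column prevalence table
#'
#' Expects a TSV with header columns `age` and `prevalence`.
#'
#' @param path File path.
#' @param subtype_fraction Passed to [prevalence_model()].
#' @return A `prevalence_model`.
#' @export
read_prevalence_table <- function(path, subtype_fraction = 0.20) {
  tab <- utils::read.delim(path, header = TRUE)
  if (!all(c("age", "prevalence") %in% names(tab)))
    stop("prevalence table needs header columns `age` and `prevalence`: ", path)
  prevalence_model(tab$age, tab$prevalence, subtype_fraction = subtype_fraction)
}

#' Write a prevalence model to TSV
#'
#' @param model A `prevalence_model`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_prevalence_table <- function(model, path) {
  stopifnot(inherits(model, "prevalence_model"))
  utils::write.table(
    data.frame(age = model$age, prevalence = model$prevalence),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
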