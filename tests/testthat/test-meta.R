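test_that("Stouffer weighted Z combination matches hand calculations", {
  # single study: identity
  one <- stouffer_meta(1.3, n = 50, weight_scheme = "n")
  expect_equal(one$z_meta, 1.3)
  expect_equal(one$p, 2 * pnorm(-1.3))

  # equal weights, z = 1.96 each -> 1.96 * sqrt(2)
  two <- stouffer_meta(c(1.96, 1.96), n_cases = c(50, 50),
                       n_controls = c(50, 50))
  expect_equal(two$z_meta, 1.96 * sqrt(2), tolerance = 1e-9)

  # weights sqrt(100), sqrt(400); z = 0, 2 -> 40 / sqrt(500)
  w <- stouffer_meta(c(0, 2), n = c(100, 400), weight_scheme = "n")
  expect_equal(w$z_meta, 40 / sqrt(500), tolerance = 1e-9)
  expect_equal(w$z_meta, 1.7889, tolerance = 1e-4)

  # k identical studies scale z by sqrt(k)
  for (k in c(2, 5, 9)) {
    rep_k <- stouffer_meta(rep(1.5, k), n_cases = rep(80, k),
                           n_controls = rep(120, k))
    expect_equal(rep_k$z_meta, 1.5 * sqrt(k), tolerance = 1e-9)
  }
  expect_error(stouffer_meta(numeric(0)), "at least one")
})

test_that("genomic control deflates by the median chi-square ratio", {
  med <- qchisq(0.5, 1)
  chisq <- c(0.1, med, 3)
  gc <- genomic_control(chisq)
  expect_equal(gc$lambda, 1)
  expect_identical(gc$corrected, chisq)

  gc2 <- genomic_control(2 * chisq)
  expect_equal(gc2$lambda, 2)
  expect_equal(median(gc2$corrected), med)

  # lambda below 1 is floored: statistics are never inflated
  gc3 <- genomic_control(0.5 * chisq)
  expect_equal(gc3$lambda, 0.5)
  expect_identical(gc3$corrected, 0.5 * chisq)
  expect_equal(genomic_control(0.5 * chisq, floor_at_one = FALSE)$corrected,
               chisq)

  set.seed(61)
  expect_true(abs(genomic_control(rchisq(5000, 1))$lambda - 1) < 0.1)
})

test_that("Cochran's Q matches the inverse-variance oracle and metafor", {
  expect_equal(cochran_q(c(1, 1, 1), c(0.5, 1, 2))$Q, 0)
  expect_equal(cochran_q(c(1, 1, 1), c(0.5, 1, 2))$p, 1)

  q2 <- cochran_q(c(0, 2), c(1, 1))
  expect_equal(q2$Q, 2)
  expect_equal(q2$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(q2$p, 0.1573, tolerance = 1e-4)

  expect_error(cochran_q(1, 1), "at least two")

  set.seed(8)
  b <- rnorm(6); s <- runif(6, 0.5, 2)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  expect_equal(cochran_q(b, s)$Q, unname(ref$QE), tolerance = 1e-8)
  expect_equal(cochran_q(b, s)$p, unname(ref$QEp), tolerance = 1e-8)

  # Q invariant under common rescaling of betas and ses
  expect_equal(cochran_q(3 * b, 3 * s)$Q, cochran_q(b, s)$Q,
               tolerance = 1e-12)
})

test_that("fixed-effects IVW pooling matches hand calculation and metafor", {
  ivw <- ivw_fixed_meta(c(1, 3), c(1, 1))
  expect_equal(ivw$beta, 2)
  expect_equal(ivw$se, sqrt(0.5), tolerance = 1e-9)
  expect_equal(ivw$se, 0.7071, tolerance = 1e-4)

  expect_equal(ivw_fixed_meta(2.2, 0.3)$beta, 2.2)
  expect_equal(ivw_fixed_meta(rep(1.5, 4), rep(0.8, 4))$se, 0.8 / 2,
               tolerance = 1e-12)

  set.seed(9)
  b <- rnorm(5); s <- runif(5, 0.3, 1.5)
  ref <- metafor::rma(yi = b, sei = s, method = "FE")
  got <- ivw_fixed_meta(b, s)
  expect_equal(got$beta, unname(as.vector(ref$beta)), tolerance = 1e-8)
  expect_equal(got$se, unname(ref$se), tolerance = 1e-8)
  # order invariance
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(ivw_fixed_meta(b[perm], s[perm])$beta, got$beta,
               tolerance = 1e-12)
})

test_that("Han-Eskin random-effects test behaves at the homogeneous limit", {
  # identical effects: tau2 collapses to 0 and the likelihood-ratio
  # statistic reduces to the squared fixed-effects z
  res <- re2_han_eskin(rep(0.4, 5), rep(0.2, 5))
  expect_equal(res$tau2, 0)
  ivw <- ivw_fixed_meta(rep(0.4, 5), rep(0.2, 5))
  expect_equal(res$stat, ivw$z^2, tolerance = 1e-6)
  expect_equal(res$mu, ivw$beta, tolerance = 1e-8)
  # the mixture null is heavier-tailed than chisq(1), so the RE2 p is
  # bounded below by half the fixed-effects p and above by chisq(2)
  expect_gte(res$p, ivw$p / 2 * (1 - 1e-9))
  expect_lte(res$p, pchisq(res$stat, 2, lower.tail = FALSE))
  expect_error(re2_han_eskin(1, 1), "at least two")
})

test_that("Han-Eskin test controls type-I error under the null", {
  set.seed(101)
  k <- 10; ses <- runif(k, 0.5, 1.5)
  hits <- 0L; reps <- 2000L
  for (i in seq_len(reps)) {
    b <- rnorm(k, 0, ses)
    res <- re2_han_eskin(b, ses)
    expect_gte(res$tau2, 0)
    if (res$p < 0.05) hits <- hits + 1L
  }
  # empirical size within the binomial 99% CI of the nominal 0.05
  expect_lt(hits / reps, 0.05 + 2.576 * sqrt(0.05 * 0.95 / reps))
})

test_that("Fisher's method combines independent p-values", {
  expect_equal(fisher_combine(0.0321), 0.0321, tolerance = 1e-12)
  expect_equal(fisher_combine(c(1, 1)), 1, tolerance = 1e-12)
  set.seed(3)
  p <- runif(4)
  expect_equal(fisher_combine(p),
               pchisq(-2 * sum(log(p)), 8, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(fisher_combine(c(0.5, 0)), "in \\(0, 1\\]")
  expect_error(fisher_combine(c(0.5, 1.2)), "in \\(0, 1\\]")
  expect_error(fisher_combine(numeric(0)), "no p-values")
})

test_that("meta_analyse harmonizes alleles and applies per-study GC", {
  set.seed(44)
  mk_scan <- function(flip = FALSE, seed = 1) {
    panel <- make_panel(n = 300, m = 40, seed = seed)
    y <- rnorm(300)
    s <- assoc_scan(panel, y, status = rep(c(1L, 0L), 150))
    if (flip) {
      s$ea <- "G"; s$oa <- "A"
      s$z <- -s$z; s$beta <- -s$beta; s$r <- -s$r
    }
    s
  }
  s1 <- mk_scan(seed = 1); s2 <- mk_scan(flip = TRUE, seed = 2)
  meta_flip <- meta_analyse(list(a = s1, b = s2), gc = FALSE)
  s2_raw <- mk_scan(flip = FALSE, seed = 2)
  meta_raw <- meta_analyse(list(a = s1, b = s2_raw), gc = FALSE)
  # flipping the allele labels and the sign leaves the meta Z unchanged
  expect_equal(meta_flip$z_meta, meta_raw$z_meta, tolerance = 1e-12)
  expect_true(all(meta_flip$case_coverage == 1))
  expect_identical(nchar(meta_flip$direction[1]), 2L)

  # conflicting allele metadata is an error naming the SNP
  s_bad <- s2_raw; s_bad$ea <- "T"; s_bad$oa <- "C"
  expect_error(meta_analyse(list(a = s1, b = s_bad)), "conflicting alleles")

  # per-study lambdas match a direct genomic_control computation
  meta_gc <- meta_analyse(list(a = s1, b = s2_raw), gc = TRUE)
  lam <- attr(meta_gc, "lambda")
  expect_length(lam, 2L)
  expect_equal(unname(lam["a"]), genomic_control(s1$chisq)$lambda,
               tolerance = 1e-12)

  # single inflated study: GC deflates each z by sqrt(lambda)
  s_inf <- s1
  s_inf$chisq <- 4 * s_inf$chisq; s_inf$z <- 2 * s_inf$z
  lam_inf <- genomic_control(s_inf$chisq)$lambda
  expect_gt(lam_inf, 1)
  m_inf <- meta_analyse(list(a = s_inf), gc = TRUE)
  expect_equal(m_inf$z_meta[order(m_inf$snp)],
               (s_inf$z / sqrt(lam_inf))[order(s_inf$snp)],
               tolerance = 1e-9)
})

test_that("case-coverage and heterogeneity filters use the stated boundaries", {
  meta <- data.frame(
    snp = sprintf("rs%d", 1:8),
    case_coverage = c(0.74, 0.75, 1, 1, 0.80, 0.60, 1, 0.75),
    q_p = c(0.5, 0.5, 0.0009, 0.001, 0.0011, 0.5, NA, 1))
  out <- suppressMessages(
    apply_meta_filters(meta, min_case_coverage = 0.75, min_q_p = 0.001))
  # brute-force application of the two rules
  expected <- meta$snp[meta$case_coverage >= 0.75 &
                         (is.na(meta$q_p) | meta$q_p > 0.001)]
  expect_identical(out$snp, expected)
  expect_true("rs2" %in% out$snp)     # coverage exactly 0.75 kept
  expect_false("rs4" %in% out$snp)    # q_p exactly 0.001 dropped
  expect_false("rs1" %in% out$snp)    # coverage 0.74 dropped
  expect_false("rs3" %in% out$snp)    # q_p 0.0009 dropped
  cnt <- attr(out, "filter_counts")
  expect_identical(unname(cnt["n_out"]), length(expected))
})

test_that("Stouffer on equal-sized studies equals unweighted z pooling", {
  z <- c(0.4, -1.1, 2.2)
  eq <- stouffer_meta(z, n_cases = rep(100, 3), n_controls = rep(150, 3))
  expect_equal(eq$z_meta, sum(z) / sqrt(3), tolerance = 1e-12)
})
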