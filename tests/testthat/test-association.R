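test_that("qc_filter discards strictly below the info and MAF thresholds", {
  # info 0.29 out, 0.30 in (boundary kept); eaf 0 out
  dos <- cbind(rep(1, 20), rep(1, 20), rep(0, 20))
  dos[1:6, 1:2] <- 0  # eaf 0.7 for snps 1-2
  panel <- make_panel(dosage = dos, info = c(0.29, 0.30, 1))
  kept <- suppressMessages(qc_filter(panel))
  expect_identical(kept$snps$snp, "rs002")

  # constructed 10-SNP fixture: 3 fail the info cut, 2 fail the MAF cut,
  # 1 of them fails both -> 6 survivors; brute-force check
  set.seed(2)
  dos10 <- matrix(rbinom(200 * 10, 2L, 0.3), ncol = 10)
  dos10[, 5] <- rbinom(200, 2L, 0.001)  # rare
  dos10[, 10] <- 0                      # monomorphic
  info10 <- rep(1, 10); info10[c(1, 2, 10)] <- 0.1
  panel10 <- make_panel(dosage = dos10, info = info10)
  eaf <- colMeans(dos10) / 2
  expected <- panel10$snps$snp[info10 >= 0.3 & pmin(eaf, 1 - eaf) >= 0.01]
  expect_length(expected, 6L)
  kept10 <- suppressMessages(qc_filter(panel10))
  expect_identical(kept10$snps$snp, expected)
  expect_identical(unname(attr(kept10, "qc_counts")["n_info"]), 3L)

  # empty result is a warning, not an error
  expect_warning(suppressMessages(qc_filter(panel, min_info = 2)),
                 "no SNPs survive")
})

test_that("residualize projects out the covariates", {
  set.seed(31)
  y <- rnorm(40)
  expect_equal(residualize(y, NULL), y - mean(y))
  x <- rnorm(40)
  expect_lt(max(abs(residualize(2 * x + 3, cbind(x)))), 1e-10)
  # hand-rolled normal-equations oracle
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(residualize(y, cbind(x)), as.vector(y - X %*% beta),
               tolerance = 1e-10)
  # residuals orthogonal to each covariate column
  C <- matrix(rnorm(40 * 3), ncol = 3)
  r <- residualize(y, C)
  expect_lt(max(abs(crossprod(C, r))), 1e-8)
  expect_error(residualize(y, cbind(a = x, b = x)), "collinear")
})

test_that("informed test statistic is N times the squared partial correlation", {
  d <- c(0, 1, 2, 0, 1, 2, 1, 0)
  res <- informed_test(d, 0.5 * d - 1)
  expect_equal(res$chisq, length(d))
  expect_equal(res$r, 1)

  # constant liability cannot be tested
  expect_identical(informed_test(d, rep(1, 8))$flag, "unestimable")
  expect_identical(informed_test(rep(2, 8), rnorm(8))$flag, "unestimable")

  # null chi-squares follow chisq(1): uniform p-values
  set.seed(55)
  panel <- make_panel(n = 500, m = 1000, seed = 55)
  y <- rnorm(500)
  scan <- assoc_scan(panel, y)
  expect_equal(scan$z^2, scan$chisq, tolerance = 1e-9)
  expect_gt(ks.test(scan$p, "punif")$p.value, 0.01)
  expect_gt(ks.test(scan$chisq, pchisq, df = 1)$p.value, 0.01)
})

test_that("informed equals uninformed when prevalence is constant in age", {
  pm <- flat_model(0.1)
  set.seed(77)
  ph <- make_phenotype(100, 100, case_ages = sample(45:85, 100, TRUE),
                       control_ages = sample(45:85, 100, TRUE))
  liab <- assign_liabilities(ph, pm, "IS")
  d <- rbinom(200, 2L, 0.4)
  inf <- informed_test(d, liab)
  uni <- uninformed_test(d, ph$status)
  expect_equal(inf$chisq, uni$chisq, tolerance = 1e-10)
})

test_that("uninformed test matches the Cochran-Armitage trend statistic", {
  # balanced, perfectly separated: chisq = N
  status <- rep(c(1L, 0L), each = 20)
  expect_equal(uninformed_test(rep(c(2, 0), each = 20), status)$chisq, 40)

  # 2x2 contingency oracle for 0/1 dosage
  set.seed(91)
  d <- rbinom(300, 1L, 0.3)
  y <- rbinom(300, 1L, plogis(-0.5 + 0.8 * d))
  tab <- table(factor(d, 0:1), factor(y, 0:1))
  N <- sum(tab); R <- sum(tab[, "1"])
  x <- c(0, 1)
  n_i <- rowSums(tab); r_i <- tab[, "1"]
  T_ <- sum(x * (r_i - n_i * R / N))
  V <- R * (N - R) / N * (sum(n_i * x^2) - sum(n_i * x)^2 / N) / N
  catt <- T_^2 / V
  expect_equal(uninformed_test(d, y)$chisq, unname(catt), tolerance = 1e-9)
})

test_that("score test is affine-invariant and allele-flip antisymmetric", {
  set.seed(13)
  d <- rbinom(150, 2L, 0.25)
  y <- 0.2 * d + rnorm(150)
  base <- informed_test(d, y)
  scaled <- informed_test(d, 3.7 * y - 11)
  expect_equal(base$chisq, scaled$chisq, tolerance = 1e-10)
  flip <- informed_test(2 - d, y)
  expect_equal(flip$z, -base$z, tolerance = 1e-10)
  expect_equal(flip$p, base$p, tolerance = 1e-12)
})

test_that("covariate adjustment removes a confounded signal", {
  set.seed(17)
  pc <- rnorm(400)
  d <- rbinom(400, 2L, plogis(pc))        # dosage loaded on the PC
  y <- pc + rnorm(400, sd = 0.2)          # response driven by the PC only
  raw <- informed_test(d, y)
  adj <- informed_test(d, y, covariates = cbind(pc))
  expect_lt(adj$chisq, raw$chisq / 2)
  expect_gt(adj$p, 0.001)
})

test_that("logistic ORs by onset quantile recover the 2x2 odds ratio", {
  # cases: 30 exposed / 70 unexposed; controls: 20 exposed / 80 unexposed
  d <- c(rep(1, 30), rep(0, 70), rep(1, 20), rep(0, 80))
  y <- rep(c(1L, 0L), each = 100)
  ages <- rep(60, 200)
  res <- logistic_or_by_quantile(d, y, ages, quantile_cuts = 65)
  expect_equal(res$or, (30 * 80) / (70 * 20), tolerance = 1e-6)
  expect_identical(res$flag, "ok")

  # independent dosage: OR near 1, inside its own CI
  set.seed(23)
  d2 <- rbinom(400, 2L, 0.3)
  y2 <- rep(c(1L, 0L), each = 200)
  res2 <- logistic_or_by_quantile(d2, y2, rep(60, 400), quantile_cuts = 65)
  expect_gt(res2$ci_hi, 1); expect_lt(res2$ci_lo, 1)

  # complete separation is flagged, not estimated
  d3 <- rep(c(2, 0), each = 25)
  y3 <- rep(c(1L, 0L), each = 25)
  res3 <- logistic_or_by_quantile(d3, y3, rep(60, 50), quantile_cuts = 65)
  expect_identical(res3$flag, "separation")
  expect_true(is.na(res3$or))

  expect_error(logistic_or_by_quantile(d, y, ages, c(65, 60)), "ascending")
})

test_that("odds ratios weaken from youngest to all-ages onset strata", {
  # one strong causal SNP; cumulative quantile ORs should be non-increasing
  # in most replicates because younger-onset cases are more genetically
  # loaded under the generative model
  monotone <- logical(50)
  for (i in seq_len(50)) {
    cfg <- sim_config(seed = 3000 + i, n_centres = 1, n_cases = 1000,
                      n_controls = 1000, m_snps = 1, n_causal = 1,
                      beta = 0.45, dosage_noise = 0)
    co <- simulate_cohort(cfg)
    ph <- co$phenotype
    cuts <- unname(quantile(ph$age[ph$status == 1L], c(0.25, 0.5, 0.75)))
    cuts <- c(cuts, Inf)
    res <- logistic_or_by_quantile(co$panels[[1L]]$dosage[, 1L], ph$status,
                                   ph$age, quantile_cuts = cuts)
    monotone[i] <- all(res$flag == "ok") && !is.unsorted(rev(res$or))
  }
  expect_gte(mean(monotone), 0.8)
})
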