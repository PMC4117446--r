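test_that("greedy LD clumping keeps index SNPs and honours the window", {
  # single SNP: itself
  one <- data.frame(snp = "rs1", chr = 1L, pos = 100L, p = 0.01)
  d1 <- matrix(rbinom(30, 2, 0.4), ncol = 1,
               dimnames = list(NULL, "rs1"))
  expect_identical(ld_clump(one, d1), "rs1")

  # three SNPs within 50 kb, pairwise r2 = 1: lowest p survives
  base <- rbinom(40, 2, 0.4)
  d3 <- cbind(rs1 = base, rs2 = base, rs3 = 2 - base)  # r2 = 1 throughout
  a3 <- data.frame(snp = c("rs1", "rs2", "rs3"), chr = 1L,
                   pos = c(100L, 20100L, 50100L), p = c(0.2, 0.01, 0.5))
  expect_identical(ld_clump(a3, d3), "rs2")

  # two SNPs 400 kb apart with r2 = 1: both survive (outside window)
  a2 <- data.frame(snp = c("rs1", "rs2"), chr = 1L,
                   pos = c(100L, 400100L), p = c(0.01, 0.2))
  d2 <- cbind(rs1 = base, rs2 = base)
  expect_identical(ld_clump(a2, d2), c("rs1", "rs2"))

  # missing SNP in the reference panel is an error naming it
  expect_error(ld_clump(a2, d1), "rs2")
})

test_that("greedy clumping agrees with an exhaustive reference implementation", {
  set.seed(202)
  for (rep in 1:10) {
    m <- 100
    blocks <- sort(sample(1:8, m, TRUE))
    latent <- matrix(rnorm(60 * 8), ncol = 8)
    dos <- sapply(seq_len(m), function(j)
      as.numeric(cut(latent[, blocks[j]] + rnorm(60, sd = runif(1, 0.1, 2)),
                     c(-Inf, -0.5, 0.5, Inf))) - 1)
    colnames(dos) <- sprintf("rs%03d", seq_len(m))
    assoc <- data.frame(snp = colnames(dos),
                        chr = sample(1:2, m, TRUE),
                        pos = sample.int(2e6, m),
                        p = round(runif(m), 3))  # rounding forces p ties
    expect_identical(ld_clump(assoc, dos, window = 250000, r2_max = 0.25),
                     brute_force_clump(assoc, dos, window = 250000,
                                       r2_max = 0.25))
  }
})

test_that("clumped set does not depend on input row order", {
  set.seed(7)
  m <- 50
  dos <- matrix(rbinom(40 * m, 2, 0.3), ncol = m,
                dimnames = list(NULL, sprintf("rs%02d", 1:m)))
  assoc <- data.frame(snp = colnames(dos), chr = 1L,
                      pos = sort(sample.int(1e6, m)),
                      p = round(runif(m), 2))
  shuffled <- assoc[sample.int(m), ]
  expect_identical(ld_clump(assoc, dos), ld_clump(shuffled, dos))
})

test_that("age permutation shuffles cases within centre and subtype only", {
  set.seed(5)
  ph <- rbind(
    make_phenotype(20, 10, centre = "A", case_ages = sample(45:85, 20, TRUE),
                   control_ages = sample(45:85, 10, TRUE), subtype = "LAA"),
    make_phenotype(15, 10, centre = "B", case_ages = sample(45:85, 15, TRUE),
                   control_ages = sample(45:85, 10, TRUE), subtype = "CE"))
  ph$sample_id <- sprintf("s%04d", seq_len(nrow(ph)))
  perm <- permute_ages(ph, seed = 11, perm_index = 1)
  # controls untouched
  expect_identical(perm$age[perm$status == 0L], ph$age[ph$status == 0L])
  # multiset of case ages preserved within each stratum
  for (cc in c("A", "B")) {
    sel <- ph$status == 1L & ph$centre == cc
    expect_identical(sort(perm$age[sel]), sort(ph$age[sel]))
  }
  # deterministic given (seed, perm_index); different index reshuffles
  expect_identical(permute_ages(ph, 11, 1), perm)
  expect_false(identical(permute_ages(ph, 11, 2)$age, perm$age))

  # a single-case stratum is left unchanged
  ph1 <- make_phenotype(1, 5, case_ages = 50)
  expect_identical(permute_ages(ph1, 3, 1)$age, ph1$age)
})

test_that("empirical p counts strictly more extreme permutations", {
  # observed more extreme than all permutations: 0 with a <1/n annotation
  ep <- empirical_p(100, rnorm(1000), direction = "greater")
  expect_identical(ep$p, 0)
  expect_identical(ep$annotation, "<0.001")

  # observed at the permutation median: about one half
  ep2 <- empirical_p(0, seq(-1, 1, length.out = 999), direction = "greater")
  expect_equal(ep2$p, 0.5, tolerance = 0.01)

  # exact ties count as not exceeding; tie count reported
  ep3 <- empirical_p(2, rep(2, 50), direction = "greater")
  expect_identical(ep3$p, 0)
  expect_identical(ep3$n_ties, 50L)

  # direction "less" for p-value-scale statistics
  ep4 <- empirical_p(0.01, c(0.5, 0.002, 0.9, 0.004), direction = "less")
  expect_equal(ep4$p, 0.5)
  expect_identical(known_locus_age_effect(0.01, c(0.5, 0.002, 0.9, 0.004))$p,
                   ep4$p)
})

test_that("per-SNP empirical p is discrete-uniform under an exchangeable null", {
  set.seed(31)
  n_perm <- 99L; n_snp <- 500L
  obs <- runif(n_snp)
  perm <- matrix(runif(n_perm * n_snp), nrow = n_perm)
  emp <- vapply(seq_len(n_snp), function(j)
    empirical_p(obs[j], perm[, j], direction = "less")$p, numeric(1))
  # p takes values r/n, r ~ uniform on {0, ..., n}
  counts <- tabulate(round(emp * n_perm) + 1L, n_perm + 1L)
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("sumZ evaluation freezes the SNP set and is monotone in it", {
  obs <- c(a = 1e-6, b = 0.002, c = 0.03, d = 0.5)
  set.seed(17)
  perm <- matrix(runif(400), ncol = 4, dimnames = list(NULL, names(obs)))
  ev <- sumz_evaluation(obs, perm, thresholds = c(0.05, 0.005, 0.0005))
  expect_identical(ev$n_snps, c(3L, 2L, 1L))
  # adding a SNP never decreases sumZ
  expect_true(all(diff(ev$sumz_obs) <= 0))
  expect_equal(ev$sumz_obs[1L],
               sum(qnorm(obs[1:3] / 2, lower.tail = FALSE)))
  # empty selection is reported, not an error
  ev0 <- sumz_evaluation(c(a = 0.9), perm[, "a", drop = FALSE],
                         thresholds = 0.05)
  expect_identical(ev0$n_snps, 0L)
  expect_error(sumz_evaluation(obs, perm, thresholds = c(0.01, 0.05)),
               "descending")
})

test_that("proportion-more-significant summarises per-permutation wins", {
  obs <- c(a = 0.01, b = 0.02)
  perm_same <- matrix(rep(c(0.01, 0.02), each = 5), ncol = 2,
                      dimnames = list(NULL, c("a", "b")))
  # identical permutations: strict inequality gives proportion 0
  expect_identical(proportion_more_significant(obs, perm_same)$median, 0)

  perm_worse <- matrix(0.5, nrow = 5, ncol = 2,
                       dimnames = list(NULL, c("a", "b")))
  res <- proportion_more_significant(obs, perm_worse)
  expect_identical(res$median, 1)
  expect_identical(res$q3 - res$q1, 0)

  set.seed(3)
  ids <- sprintf("s%02d", 1:20)
  perm_null <- matrix(runif(2000 * 20), ncol = 20,
                      dimnames = list(NULL, ids))
  obs_null <- setNames(runif(20), ids)
  res_null <- proportion_more_significant(obs_null, perm_null)
  expect_equal(res_null$median, mean(1 - obs_null), tolerance = 0.1)
})

test_that("permutation machinery reproduces exactly from the master seed", {
  cfg <- sim_config(seed = 41, n_centres = 2, n_cases = 80, n_controls = 80,
                    m_snps = 30, n_causal = 3, beta = 0.2)
  co <- simulate_cohort(cfg)
  p1 <- permutation_pvalues(co$panels, co$phenotype, co$model, "IS",
                            n_perm = 5, seed = 9)
  p2 <- permutation_pvalues(co$panels, co$phenotype, co$model, "IS",
                            n_perm = 5, seed = 9)
  expect_identical(p1, p2)
  # fast path agrees with the general scan on each permutation
  ph3 <- permute_ages(co$phenotype, seed = 9, perm_index = 3)
  ref <- informed_meta_scan(co$panels, ph3, co$model, "IS", gc = FALSE)
  expect_equal(unname(p1[3, ref$snp]), ref$p_meta, tolerance = 1e-12)
})
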