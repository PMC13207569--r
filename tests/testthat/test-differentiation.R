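test_that("squared genotypic distances match direct enumeration", {
  dm <- make_dm(rbind(c(2L, 0L), c(0L, 1L), c(1L, 2L)), groups = rep("A", 3))
  d2 <- genotype_distance_matrix(dm)
  brute <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    brute[i, j] <- sum((dm$dosage[i, ] - dm$dosage[j, ])^2)
  expect_equal(unname(d2), brute)
  expect_equal(d2[1, 2], 4 + 1)   # opposite homozygotes + hom-vs-het
  expect_equal(diag(d2), c(s001 = 0, s002 = 0, s003 = 0))
})

test_that("PhiPT equals the hand AMOVA on the worked toys", {
  # complete fixation for opposite alleles
  dm <- make_dm(matrix(c(2L, 2L, 0L, 0L), ncol = 1),
                groups = c("A", "A", "B", "B"))
  expect_equal(phi_pt(dm, "subpop", n_perm = 0)$phi, 1)

  # {2,1} vs {0,1}: SS_total 2, SS_within 1, n0 = 2, Va 0.25, Vw 0.5
  dm2 <- make_dm(matrix(c(2L, 1L, 0L, 1L), ncol = 1),
                 groups = c("A", "A", "B", "B"))
  r <- phi_pt(dm2, "subpop", n_perm = 0)
  expect_equal(r$SS_total, 2)
  expect_equal(r$SS_within, 1)
  expect_equal(r$Va, 0.25)
  expect_equal(r$Vw, 0.5)
  expect_equal(r$phi, 1 / 3)
  expect_equal(r$df_among, 1L)
  expect_equal(r$df_within, 2L)
})

test_that("identical populations give PhiPT 0 after truncation", {
  dm <- make_dm(matrix(c(2L, 1L, 0L, 2L, 1L, 0L), ncol = 1),
                groups = rep(c("A", "B"), each = 3))
  r <- phi_pt(dm, "subpop", n_perm = 99, seed = 2)
  expect_equal(r$phi, 0)
  expect_lte(r$phi_raw, 0)
  expect_gt(r$p_perm, 0.05)
})

test_that("undersized populations are refused by name", {
  dm <- make_dm(matrix(c(1L, 0L, 2L), ncol = 1), groups = c("A", "B", "B"))
  expect_error(phi_pt(dm, "subpop"), "A")
})

test_that("PhiPT recovers the theoretical AMOVA expectation 2F/(1+F)", {
  for (f in c(0.05, 0.15, 0.25)) {
    ds <- simulate_dataset(sim_config(n_pops = 2, pop_sizes = 200,
                                      n_loci = 500, fst = f, seed = 1))
    phi <- phi_pt(ds$dosage, "subpop", n_perm = 0)$phi
    expect_lt(abs(phi - 2 * f / (1 + f)), 0.05)
  }
})

test_that("Nei distance matches hand arithmetic and is symmetric", {
  fr <- make_freqs(rbind(c(0.5), c(0.5)), chroms = 20)
  expect_equal(nei_distance(fr)[1, 2], 0)

  fr2 <- make_freqs(rbind(0.9, 0.1), chroms = 10)
  expect_equal(nei_distance(fr2)[1, 2], -log(0.18 / 0.82), tolerance = 1e-12)

  set.seed(8)
  fr3 <- make_freqs(matrix(runif(4 * 30), 4, 30), chroms = 40)
  D <- nei_distance(fr3)
  expect_equal(D, t(D))
  expect_equal(diag(D), setNames(rep(0, 4), rownames(D)))
  Du <- nei_distance(fr3, unbiased = TRUE)
  expect_equal(Du, t(Du))
})

test_that("exact G-test agrees with enumeration oracle and the Markov chain", {
  tab <- rbind(c(8, 2), c(2, 8))
  g <- locusdiff:::g_statistic(tab)
  expect_equal(g, 2 * (16 * log(1.6) + 4 * log(0.4)), tolerance = 1e-12)
  p_enum <- locusdiff:::enumerate_exact_p(tab, g)
  expect_equal(p_enum, oracle_g_exact_p(tab), tolerance = 1e-12)
  mc <- locusdiff:::mcmc_exact_p(tab, g, dememorization = 10000,
                                 batches = 100, iter_per_batch = 5000,
                                 seed = 3)
  expect_lt(abs(mc$p - p_enum), 3 * mc$se + 1e-9)
})

test_that("G-test handles degenerate and monomorphic loci", {
  # identical columns: G = 0, p = 1
  dm <- make_dm(rbind(c(2L, 0L), c(0L, 0L), c(2L, 0L), c(0L, 0L)),
                groups = c("A", "A", "B", "B"))
  res <- exact_g_test(dm, "subpop", c("A", "B"), seed = 1)
  loc1 <- res$per_locus[res$per_locus$rsid == "snp0001", ]
  expect_equal(loc1$G, 0, tolerance = 1e-12)
  expect_equal(loc1$p, 1)
  # locus fixed for the same allele in both: skipped, no df contributed
  loc2 <- res$per_locus[res$per_locus$rsid == "snp0002", ]
  expect_true(loc2$skipped)
  expect_equal(res$combined$df, 2L)
})

test_that("Fisher combination accumulates evidence from significant loci", {
  comb <- function(ps) stats::pchisq(-2 * sum(log(ps)), 2 * length(ps),
                                     lower.tail = FALSE)
  # strongly significant loci always sharpen the combined p...
  ps <- c(0.04, 0.01)
  prev <- comb(ps)
  for (p in c(0.02, 0.005, 0.03)) {
    ps <- c(ps, p)
    cur <- comb(ps)
    expect_lt(cur, prev)
    prev <- cur
  }
  # ...while an uninformative locus (p near 1) costs degrees of freedom and
  # weakens it; skipping such loci entirely (no df) is what the per-locus
  # skip rule guarantees
  expect_gt(comb(c(ps, 0.99)), comb(ps))

  # the combined statistic matches its definition on a pipeline result
  dm <- make_dm(rbind(c(2L, 2L), c(2L, 1L), c(0L, 0L), c(0L, 1L)),
                groups = c("A", "A", "B", "B"))
  res <- exact_g_test(dm, "subpop", c("A", "B"), seed = 7)
  inf <- res$per_locus[!res$per_locus$skipped, ]
  expect_equal(res$combined$X2, -2 * sum(log(inf$p)))
  expect_equal(res$combined$df, 2L * nrow(inf))
})

test_that("genotypic flavor builds 3x2 tables and detects differentiation", {
  ds <- simulate_dataset(sim_config(n_pops = 2, pop_sizes = 50, n_loci = 10,
                                    fst = 0.3, seed = 14))
  res <- exact_g_test(ds$dosage, "subpop", c("POP1", "POP2"),
                      flavor = "genotypic", seed = 5)
  expect_true(all(res$per_locus$p[!res$per_locus$skipped] > 0))
  expect_true(res$combined$p < 0.05)
})

test_that("principal coordinates reproduce classic geometries", {
  # two points at distance d: coordinates +-d/2 on axis 1
  d <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  pc <- pcoa(d)
  expect_equal(sort(pc$points[, 1]), c(a = -1.5, b = 1.5),
               ignore_attr = TRUE)

  # 3-4-5 right triangle: embedded distances reproduce the input exactly
  d3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d3["a", "b"] <- d3["b", "a"] <- 3
  d3["a", "c"] <- d3["c", "a"] <- 4
  d3["b", "c"] <- d3["c", "b"] <- 5
  pc3 <- pcoa(d3)
  rec <- as.matrix(dist(pc3$points))
  expect_equal(unname(rec), unname(d3), tolerance = 1e-9)
  expect_true(all(diff(pc3$eig[seq_along(pc3$percent)]) <= 1e-9))
  expect_equal(sum(pc3$percent), 100)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("relabeling permutes principal coordinates identically", {
  set.seed(15)
  x <- matrix(rnorm(12), 4)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  pc <- pcoa(d)
  perm <- c(3, 1, 4, 2)
  pc_p <- pcoa(d[perm, perm])
  expect_equal(abs(pc_p$points), abs(pc$points[perm, ]), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("a divergent population lands farthest out on the first axis", {
  ds <- simulate_dataset(sim_config(n_pops = 3, pop_sizes = 60, n_loci = 150,
                                    fst = c(0.3, 0.02, 0.02), seed = 16))
  dmx <- differentiation_matrix(ds$dosage, "subpop", n_perm = 0)
  pc <- pcoa(dmx$phi)
  centered <- abs(pc$points[, 1] - mean(pc$points[, 1]))
  expect_equal(names(which.max(centered)), "POP1")
})

test_that("combined matrix carries PhiPT below and Nei above the diagonal", {
  ds <- simulate_dataset(sim_config(n_pops = 3, pop_sizes = 30, n_loci = 60,
                                    fst = 0.2, seed = 17))
  dmx <- differentiation_matrix(ds$dosage, "subpop", n_perm = 49, seed = 3)
  cm <- dmx$combined
  expect_equal(cm[lower.tri(cm)], dmx$phi[lower.tri(dmx$phi)])
  expect_equal(cm[upper.tri(cm)], dmx$nei[upper.tri(dmx$nei)])
  expect_equal(diag(cm), setNames(rep(0, 3), rownames(cm)))
  expect_true(all(dmx$phi_p[lower.tri(dmx$phi_p)] > 0))
})
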