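test_that("log-CPM transform follows its defining formula", {
  counts <- matrix(c(0, 10, 999990, 5, 5, 999990), ncol = 2,
                   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  lx <- logcpm_transform(counts)
  expect_equal(lx["g1", "s1"], log2(0.5 / (1e6 + 1) * 1e6))
  expect_equal(lx["g1", "s1"], -1, tolerance = 1e-4)

  # doubling counts and library barely changes values once counts are large
  big <- matrix(c(5000, 12000, 983000, 7000, 11000, 982000), ncol = 2,
                dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  expect_lt(max(abs(logcpm_transform(2 * big) - logcpm_transform(big))),
            1e-3)

  # proportional samples give near-identical profiles
  cc <- cbind(a = c(100, 200, 700), b = 10 * c(100, 200, 700))
  lxp <- logcpm_transform(cc)
  expect_equal(lxp[, "a"], lxp[, "b"], tolerance = 1e-2,
               ignore_attr = TRUE)

  # agrees with the standard log-CPM implementation
  if (requireNamespace("edgeR", quietly = TRUE)) {
    ref <- edgeR::cpm(counts, log = TRUE, prior.count = 0.5)
    expect_equal(unname(lx), unname(ref), tolerance = 0.02)
  }
  expect_error(logcpm_transform(matrix(-1)), "nonnegative")
  expect_error(logcpm_transform(matrix(c(1, 0), 1)), "library")
})

test_that("templates are unit-norm with hand-computed pairwise cosines", {
  # 2 classes x 1 marker: templates (1,-1)/sqrt(2) and (-1,1)/sqrt(2)
  t2 <- build_templates(list(A = "g1", B = "g2"))
  expect_equal(colSums(t2^2), c(A = 1, B = 1))
  expect_equal(unname(t2[, "A"]), c(1, -1) / sqrt(2))
  expect_equal(sum(t2[, "A"] * t2[, "B"]), -1)   # antiparallel pair

  # 3 classes x 2 markers: pairwise cosine (2 - 4)/6 = -1/3 by hand
  t3 <- build_templates(list(A = c("a1", "a2"), B = c("b1", "b2"),
                             C = c("c1", "c2")))
  expect_equal(unname(colSums(t3^2)), c(1, 1, 1))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3)))
    expect_equal(sum(t3[, pair[1]] * t3[, pair[2]]), -1 / 3)

  expect_error(signature_set(list(A = "g1", B = "g1")), "exactly one")
  expect_error(build_templates(list(A = character(), B = "g")), "class")
})

test_that("classification distance behaves like cosine distance", {
  sig <- list(A = c("g1", "g2"), B = c("g3", "g4"))
  tmpl <- build_templates(sig)

  # profile equal to a template: distance 0, that class assigned
  prof <- setNames(tmpl[, "A"], rownames(tmpl))
  call <- ntp_classify(prof, sig, n_perm = 10, seed = 1)
  expect_equal(call$class, "A")
  expect_equal(call$distance, 0, tolerance = 1e-12)

  # profile orthogonal to both templates: distances all 1 (tie, flagged)
  orth <- setNames(c(1, -1, 1, -1), rownames(tmpl))
  expect_equal(sum(orth * tmpl[, "A"]), 0)
  call2 <- ntp_classify(orth, sig, n_perm = 10, seed = 1)
  expect_equal(call2$distance, 1)
  expect_true(call2$tie)

  # cosine distance is invariant to positive rescaling of the profile
  noisy <- setNames(c(1.2, 0.8, -0.9, -1.1), rownames(tmpl))
  c1 <- ntp_classify(noisy, sig, n_perm = 50, seed = 2)
  c2 <- ntp_classify(noisy * 7.3, sig, n_perm = 50, seed = 2)
  expect_equal(c1$distance, c2$distance)
  expect_equal(c1$p_value, c2$p_value)

  expect_error(ntp_classify(setNames(1, "g1"), sig), "2 marker genes")
})

test_that("permutation p matches exhaustive enumeration on a 4-marker toy", {
  sig <- list(A = c("g1", "g2"), B = c("g3", "g4"))
  tmpl <- build_templates(sig)
  set.seed(5)
  for (i in 1:3) {
    prof <- setNames(rnorm(4), rownames(tmpl))
    exact <- oracle_ntp_exhaustive_p(prof, tmpl)
    mc <- ntp_classify(prof, sig, n_perm = 10000, seed = i)$p_value
    tol <- 4 * sqrt(exact * (1 - exact) / 10000) + 2 / 10001
    expect_lt(abs(mc - exact), max(tol, 0.02))
  }
})

test_that("null permutation p-values are approximately uniform", {
  sig <- list(A = sprintf("a%02d", 1:6), B = sprintf("b%02d", 1:6))
  set.seed(99)
  profs <- matrix(rnorm(12 * 100), nrow = 12,
                  dimnames = list(c(sig$A, sig$B), sprintf("s%03d", 1:100)))
  calls <- ntp_classify(profs, sig, n_perm = 500, seed = 1)
  ks <- suppressWarnings(ks.test(calls$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("BH adjustment equals the literal step-up on random vectors", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  for (s in 1:100) {
    set.seed(s)
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    adj <- bh_fdr(p)
    expect_equal(adj, oracle_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("subtype-phenotype association is tie-corrected Kruskal-Wallis", {
  # identical value multisets across classes: no signal
  r0 <- subtype_phenotype_association(rep(c("a", "b"), each = 3),
                                      c(1, 2, 3, 1, 2, 3))
  expect_equal(r0$h, 0, tolerance = 1e-12)
  expect_gt(r0$p, 0.99)

  # separated classes against the rank-sum oracle
  v <- c(1, 2, 3, 10, 11, 12)
  g <- rep(c("lo", "hi"), each = 3)
  got <- subtype_phenotype_association(g, v)
  want <- oracle_kruskal(v, g)
  expect_equal(got$h, want$h, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)

  # heavy ties against the oracle
  v2 <- c(1, 1, 2, 2, 2, 3, 3, 1)
  g2 <- rep(c("a", "b"), 4)
  got2 <- subtype_phenotype_association(g2, v2)
  want2 <- oracle_kruskal(v2, g2)
  expect_equal(got2$h, want2$h, tolerance = 1e-10)

  # all observations tied: H defined as 0, no division error
  rt <- subtype_phenotype_association(c("a", "a", "b", "b"), rep(5, 4))
  expect_equal(rt$h, 0)
  expect_equal(rt$p, 1)

  expect_error(subtype_phenotype_association(c("a", "a"), 1:2), "2 classes")
})
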