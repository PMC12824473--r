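test_that("gene-wise standardization centers, scales, drops constants", {
  m <- rbind(a = c(1, 2, 3), b = c(10, 30, 20))
  s <- standardize_expression(m)
  expect_equal(unname(s["a", ]), c(-1, 0, 1))
  expect_equal(unname(rowMeans(s)), c(0, 0))
  expect_equal(unname(apply(s, 1, sd)), c(1, 1))

  # idempotence
  expect_equal(standardize_expression(s), s, tolerance = 1e-12)

  # constant gene dropped with warning listing it
  m2 <- rbind(m, flatgene = c(5, 5, 5))
  expect_warning(s2 <- standardize_expression(m2), "flatgene")
  expect_equal(rownames(s2), c("a", "b"))
  expect_error(suppressWarnings(
    standardize_expression(rbind(x = c(1, 1, 1)))), "zero variance")
})

test_that("elastic net fit matches an independent coordinate-descent solver", {
  # constant response: analytic minimum at beta = 0, intercept = mean(y)
  x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
  f0 <- fit_elastic_net(x, rep(0.5, 10), alpha = 0.5, lambda = 0.1)
  expect_equal(unname(f0$beta), c(0, 0, 0))
  expect_equal(f0$intercept, 0.5)

  # large penalty shrinks everything to zero
  set.seed(3)
  y <- rnorm(10)
  fbig <- fit_elastic_net(x, y, alpha = 0.5, lambda = 1e4)
  expect_equal(unname(fbig$beta), c(0, 0, 0))

  # single standardized gene collinear with y, small penalty
  set.seed(7)
  g <- as.numeric(scale(rnorm(10)))
  y1 <- 0.3 * g
  x1 <- matrix(g, ncol = 1, dimnames = list(NULL, "g"))
  got <- fit_elastic_net(x1, y1, alpha = 0.5, lambda = 0.01)
  want <- oracle_elastic_net(x1, y1, alpha = 0.5, lambda = 0.01)
  expect_gt(got$beta[["g"]], 0)
  expect_equal(unname(got$beta), want$beta, tolerance = 1e-6)

  # multi-gene random problem against the oracle
  set.seed(11)
  xm <- scale(matrix(rnorm(10 * 4), 10, 4))
  attr(xm, "scaled:center") <- attr(xm, "scaled:scale") <- NULL
  colnames(xm) <- paste0("g", 1:4)
  ym <- xm %*% c(0.5, -0.3, 0, 0) + rnorm(10, 0, 0.1)
  for (lam in c(0.02, 0.1)) {
    got <- fit_elastic_net(xm, as.numeric(ym), alpha = 0.5, lambda = lam)
    want <- oracle_elastic_net(xm, as.numeric(ym), alpha = 0.5, lambda = lam)
    expect_equal(unname(got$beta), want$beta, tolerance = 1e-5)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-5)
  }

  expect_error(fit_elastic_net(x, rnorm(5), 0.5, 0.1), "mismatch")
  expect_error(fit_elastic_net(x, c(rnorm(9), NA), 0.5, 0.1), "finite")
})

test_that("bootstrap stability scores are frequencies that sum to one", {
  co <- simulate_cohort(seed = 3, n_genes = 60, planted = 3)
  lx <- logcpm_transform(co$expression$counts)
  x <- t(suppressWarnings(standardize_expression(lx)))
  y <- co$true_nauc[rownames(x)]
  cfg <- en_config(n_bootstrap = 25, seed = 9)
  tab <- bootstrap_stability(x, y, cfg)

  expect_equal(tab$freq_pos + tab$freq_neg + tab$freq_zero,
               rep(1, nrow(tab)))
  expect_true(all(tab$score >= 0 & tab$score <= 1))
  expect_equal(tab$score, pmax(tab$freq_pos, tab$freq_neg))
  expect_equal(tab$selected, tab$score >= 0.7)

  # full reproducibility under identical config + seed
  expect_identical(tab, bootstrap_stability(x, y, cfg))
  # a different seed gives different resamples
  tab2 <- bootstrap_stability(x, y, en_config(n_bootstrap = 25, seed = 10))
  expect_false(identical(tab$score, tab2$score))

  expect_error(bootstrap_stability(x[1:3, ], y[1:3], cfg), "4 samples")
})

test_that("raising the planted effect never lowers planted-gene scores", {
  scores_at <- function(effect) {
    co <- simulate_cohort(seed = 21, n_genes = 120, planted = 3,
                          effect = effect)
    lx <- logcpm_transform(co$expression$counts)
    x <- t(suppressWarnings(standardize_expression(lx)))
    y <- co$true_nauc[rownames(x)]
    tab <- bootstrap_stability(x, y, en_config(n_bootstrap = 30, seed = 5))
    mean(tab$score[match(co$expression$planted$gene, tab$gene)])
  }
  s <- vapply(c(0.5, 3, 8), scores_at, numeric(1))
  expect_true(all(diff(s) >= -0.05))   # monotone up to resampling jitter
  expect_gt(s[3], s[1])
})

test_that("gene retention at the threshold is inclusive and fully ordered", {
  tab <- data.frame(gene = c("c", "a", "b", "d"),
                    score = c(0.69, 0.70, 0.71, 0.70),
                    mean_coefficient = c(1, 0.2, 0.5, 0.9))
  sel <- select_genes(tab, threshold = 0.7)
  expect_equal(nrow(sel), 3)            # 0.69 excluded, 0.70 kept
  expect_equal(sel$gene, c("b", "d", "a"))

  # brute-force sort oracle on random tie-heavy tables
  for (s in 1:10) {
    set.seed(s)
    n <- 30
    tb <- data.frame(gene = sprintf("g%02d", sample(n)),
                     score = sample(seq(0, 1, 0.25), n, TRUE),
                     mean_coefficient = sample(c(-1, 0, 1, 2), n, TRUE))
    got <- select_genes(tb, 0.5)
    keep <- tb[tb$score >= 0.5, ]
    want <- keep[order(-keep$score, -abs(keep$mean_coefficient),
                       keep$gene), ]
    expect_equal(got$gene, want$gene)
  }
  expect_error(select_genes(tab, 1.5), "threshold")

  # all-zero scores retain nothing
  expect_equal(nrow(select_genes(data.frame(gene = "a", score = 0,
                                            mean_coefficient = 0), 0.7)), 0)
})

test_that("gene-phenotype correlation is plain Pearson", {
  expect_equal(gene_phenotype_correlation(1:4, 1:4), 1)
  expect_equal(gene_phenotype_correlation(1:4, -(1:4)), -1)
  expect_equal(gene_phenotype_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_equal(gene_phenotype_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)),
               oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)))
  expect_error(gene_phenotype_correlation(c(1, 1, 1), 1:3), "variance")
  expect_error(gene_phenotype_correlation(1:2, 1:2), "3 paired")
})
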