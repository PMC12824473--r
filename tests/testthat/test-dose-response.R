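make_table <- function(readouts, activities = c(0, 10, 20), line = "L1",
                       rep = 1L) {
  data.frame(cell_line = line, replicate = rep,
             activity_mbq_per_ml = activities, readout = readouts)
}

test_that("normalization divides by the untreated control", {
  # flat readouts -> all fractions 1
  t1 <- normalize_viability(make_table(c(2, 2, 2)))
  expect_equal(t1$fraction, c(1, 1, 1))

  # hand-checked division, including a zero readout
  t2 <- normalize_viability(make_table(c(2.0, 1.0, 0.5)))
  expect_equal(t2$fraction, c(1, 0.5, 0.25))
  expect_equal(normalize_viability(make_table(c(2, 0, 1)))$fraction[2], 0)

  # unit invariance: any positive rescaling of raw readouts cancels
  t3 <- normalize_viability(make_table(c(2.0, 1.0, 0.5) * 37.2))
  expect_equal(t3$fraction, t2$fraction)

  # errors name the offending (line, replicate)
  bad <- make_table(c(1, 2), activities = c(5, 10), line = "SK", rep = 3L)
  expect_error(normalize_viability(bad), "SK.*replicate 3")
  expect_error(normalize_viability(make_table(c(0, 1, 2))), "untreated")
})

test_that("trapezoid rule is exact on piecewise-linear curves", {
  expect_equal(trapezoid_auc(c(0, 20), c(1, 1)), 20)
  expect_equal(trapezoid_auc(c(0, 10, 20), c(1, 0.5, 0.5)), 12.5)
  # linear curve on any grid containing the endpoints
  for (grid in list(c(0, 20), c(0, 5, 20), seq(0, 20, by = 2.5))) {
    expect_equal(trapezoid_auc(grid, 1 - grid / 20), 10)
  }
  # cross-check against an independent trapezoid implementation
  x <- sort(runif(20, 0, 20)); y <- runif(20)
  expect_equal(trapezoid_auc(x, y), pracma::trapz(x, y), tolerance = 1e-12)
  expect_error(trapezoid_auc(0, 1), "2 points")
  expect_error(trapezoid_auc(c(0, 5, 5), c(1, 1, 1)), "increasing")
})

test_that("nAUC is area over span, bounded by 1 for sub-unit curves", {
  expect_equal(nauc(20, 20), 1)
  expect_equal(nauc(12.5, 20), 0.625)
  expect_error(nauc(5, 0), "span")
  # any curve with fractions <= 1 has nAUC <= 1 (property over random curves)
  for (s in 1:20) {
    set.seed(s)
    y <- runif(8)
    expect_lte(nauc(trapezoid_auc(default_activities(), y), 20), 1)
  }
})

test_that("replicate nAUC summaries give mean and SEM per line", {
  r <- data.frame(cell_line = rep(c("a", "b"), c(3, 2)),
                  nauc = c(0.5, 0.5, 0.5, 0.4, 0.6))
  s <- summarize_nauc(r)
  expect_equal(s$mean_nauc[s$cell_line == "a"], 0.5)
  expect_equal(s$sem[s$cell_line == "a"], 0)
  expect_equal(s$mean_nauc[s$cell_line == "b"], 0.5)
  expect_equal(s$sem[s$cell_line == "b"], sd(c(0.4, 0.6)) / sqrt(2))
  expect_equal(s$sem[s$cell_line == "b"], 0.1)

  expect_warning(s1 <- summarize_nauc(data.frame(cell_line = "c",
                                                 nauc = 0.7)),
                 "single replicate")
  expect_equal(s1$sem, 0)
  expect_equal(s1$mean_nauc, 0.7)
  expect_error(summarize_nauc(data.frame(cell_line = character(),
                                         nauc = numeric())), "empty")
})

test_that("nAUC values above 1 are flagged, not clamped", {
  tab <- make_table(c(1, 1.3, 1.2))   # noise pushes fractions above 1
  reps <- compute_replicate_nauc(tab)
  expect_gt(reps$nauc, 1)
  expect_true(reps$exceeds_one)
})

test_that("Z-score grouping reproduces the study's 5/3/2 partition", {
  printed <- c("SK-Hep1" = 0.915, "SNU-449" = 0.877, "SNU-475" = 0.842,
               "SNU-423" = 0.782, "SNU-387" = 0.733, "MHCC-97H" = 0.702,
               "SNU-398" = 0.685, "Hep3B" = 0.669, "HepG2" = 0.655,
               "PLC/PRF/5" = 0.446)
  g <- assign_groups(printed)
  expect_equal(sum(g$group == "resistant"), 5)
  expect_equal(sum(g$group == "sensitive"), 3)
  expect_equal(sum(g$group == "intermediate"), 2)
  expect_setequal(g$cell_line[g$group == "resistant"],
                  c("SK-Hep1", "SNU-449", "SNU-475", "SNU-423", "SNU-387"))
  expect_setequal(g$cell_line[g$group == "sensitive"],
                  c("Hep3B", "HepG2", "PLC/PRF/5"))
  # z-scores over lines have mean 0, SD 1
  expect_equal(mean(g$z), 0)
  expect_equal(sd(g$z), 1)

  expect_error(assign_groups(c(a = 0.5, b = 0.5)), "zero variance")
  two <- assign_groups(c(a = 0, b = 1))
  expect_equal(two$z, c(-1, 1) / sqrt(2))
  expect_equal(two$group, c("sensitive", "resistant"))
})

test_that("one-way ANOVA and Tukey agree with sum-of-squares oracle", {
  # identical groups: no between-group signal
  r0 <- compare_lines_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r0$f, 0)
  expect_equal(r0$p, 1)

  # zero within-group variance handled without division error
  rz <- suppressWarnings(
    compare_lines_anova(c(0, 0, 0, 1, 1, 1), rep(c("a", "b"), each = 3)))
  expect_lt(rz$p, 1e-12)

  # fixed 3 x 3 table against the textbook decomposition
  v <- c(4.1, 3.9, 4.4, 5.0, 5.2, 4.8, 6.1, 5.8, 6.3)
  g <- rep(c("x", "y", "z"), each = 3)
  got <- compare_lines_anova(v, g)
  want <- oracle_anova(v, g)
  expect_equal(got$f, want$f, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  tk <- got$tukey
  expect_equal(tk$p_adj[tk$comparison == "y-x"],
               oracle_tukey_pair(v, g, "x", "y"), tolerance = 1e-10)

  expect_error(compare_lines_anova(c(1, 2, 3), c("a", "a", "b")),
               "2 replicates")
})

test_that("ANOVA matches the brute-force oracle on random tables", {
  for (s in 1:20) {
    set.seed(s)
    k <- sample(2:4, 1)
    n <- sample(2:5, k, replace = TRUE)
    g <- rep(paste0("g", seq_len(k)), n)
    v <- rnorm(sum(n), mean = rep(rnorm(k), n))
    got <- compare_lines_anova(v, g)
    want <- oracle_anova(v, g)
    expect_equal(got$f, want$f, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
  }
})
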