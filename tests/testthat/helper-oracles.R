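# Independent brute-force oracles used to cross-check package results.
# These deliberately re-derive each statistic from first principles and
# share no code with the implementation under test.

# naive elastic net by cyclic coordinate descent on the glmnet objective:
# (1/2n)||y - b0 - X b||^2 + lambda (alpha ||b||_1 + (1-alpha)/2 ||b||_2^2)
oracle_elastic_net <- function(x, y, alpha, lambda, tol = 1e-12,
                               max_iter = 10000) {
  n <- nrow(x); p <- ncol(x)
  beta <- numeric(p)
  b0 <- mean(y)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    old <- c(b0, beta)
    r <- y - b0 - x %*% beta
    b0 <- b0 + mean(r)
    for (j in seq_len(p)) {
      r <- y - b0 - x %*% beta
      zj <- sum(x[, j] * (r + x[, j] * beta[j])) / n
      beta[j] <- soft(zj, lambda * alpha) /
        (sum(x[, j]^2) / n + lambda * (1 - alpha))
    }
    if (max(abs(c(b0, beta) - old)) < tol) break
  }
  list(beta = beta, intercept = b0)
}

# one-way ANOVA from raw sums of squares
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ss_between <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ss_within <- sum(unlist(lapply(split(values, groups), function(v)
    (v - mean(v))^2)))
  df_b <- nlevels(groups) - 1
  df_w <- length(values) - nlevels(groups)
  f <- (ss_between / df_b) / (ss_within / df_w)
  list(f = f, p = stats::pf(f, df_b, df_w, lower.tail = FALSE),
       ms_within = ss_within / df_w, df_within = df_w)
}

# Tukey HSD adjusted p for one pair, from the studentized range distribution
oracle_tukey_pair <- function(values, groups, a, b) {
  groups <- factor(groups)
  an <- oracle_anova(values, groups)
  na <- sum(groups == a); nb <- sum(groups == b)
  diff <- mean(values[groups == b]) - mean(values[groups == a])
  se <- sqrt(an$ms_within / 2 * (1 / na + 1 / nb))
  stats::ptukey(abs(diff) / se, nlevels(groups), an$df_within,
                lower.tail = FALSE)
}

# Kruskal-Wallis H with tie correction, from ranks
oracle_kruskal <- function(values, groups) {
  groups <- factor(groups)
  n <- length(values)
  r <- rank(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(v) length(v) * mean(v)^2)) - 3 * (n + 1)
  ties <- table(values)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(h = h, p = stats::pchisq(h, nlevels(groups) - 1, lower.tail = FALSE))
}

# Pearson r from the covariance formula
oracle_pearson <- function(x, y) {
  mean((x - mean(x)) * (y - mean(y))) /
    sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# exhaustive NTP permutation p-value on a tiny marker universe:
# every permutation of the profile over the m marker genes, minimum cosine
# distance over all templates, add-one counting to mirror the estimator
oracle_ntp_exhaustive_p <- function(profile, templates) {
  m <- length(profile)
  perms <- gtools_permutations(m)
  u <- profile / sqrt(sum(profile^2))
  mind <- function(v) min(1 - as.numeric(crossprod(v, templates)))
  obs <- mind(u)
  null <- apply(perms, 1, function(ix) mind(u[ix]))
  sum(null <= obs + 1e-9) / length(null)
}

# all permutations of 1..n (small n only), no extra packages
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- gtools_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}
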