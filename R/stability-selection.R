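#' Standardize a log-scale expression matrix gene-wise
#'
#' Centers and scales each gene row to mean 0, SD 1 (sample SD, n - 1).
#' Zero-variance genes cannot be standardized; they are dropped with a
#' warning that lists them.
#'
#' @param mat genes x samples numeric matrix on a log scale.
#' @return standardized matrix, possibly with fewer rows.
#' @export
standardize_expression <- function(mat) {
  stop_if(ncol(mat) < 2, "need at least 2 samples")
  sds <- apply(mat, 1, sd)
  drop <- sds == 0 | !is.finite(sds)
  stop_if(all(drop), "all genes have zero variance")
  if (any(drop))
    warning("dropping ", sum(drop), " zero-variance gene(s): ",
            paste(rownames(mat)[drop], collapse = ", "), call. = FALSE)
  mat <- mat[!drop, , drop = FALSE]
  t(scale(t(mat)))[, , drop = FALSE]
}

#' Elastic-net configuration
#'
#' Settings for the bootstrap elastic-net stability selection: number of
#' bootstrap resamples, L1/L2 mixing, the per-resample penalty rule (inner
#' cross-validation by default, or a fixed penalty), the retention score
#' threshold, and the seed.
#'
#' @param n_bootstrap number of bootstrap resamples B (>= 1).
#' @param alpha elastic-net mixing in (0, 1]; 1 = lasso. The ridge-dominated
#'   default (0.1) keeps groups of mutually correlated predictive genes in
#'   the model together, which sign-frequency scoring requires: with
#'   lasso-leaning mixing, correlated true genes alternate across resamples
#'   and none reaches a high score.
#' @param nfolds inner cross-validation folds for per-resample penalty
#'   selection (ignored when `lambda` is fixed).
#' @param lambda fixed penalty, or `NULL` to select by inner CV per resample.
#' @param score_threshold retention threshold on the sign-frequency score.
#' @param seed integer seed.
#' @return validated configuration list.
#' @export
en_config <- function(n_bootstrap = 100, alpha = 0.1, nfolds = 3,
                      lambda = NULL, score_threshold = 0.7, seed = 1L) {
  stop_if(n_bootstrap < 1, "n_bootstrap must be >= 1")
  stop_if(alpha <= 0 || alpha > 1, "alpha must be in (0, 1]")
  stop_if(score_threshold < 0 || score_threshold > 1,
          "score_threshold must be in [0, 1]")
  list(n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
       nfolds = as.integer(nfolds), lambda = lambda,
       score_threshold = score_threshold, seed = as.integer(seed))
}

#' Fit one elastic net
#'
#' Minimizes (1/2n) ||y - X b - b0||^2 + lambda [alpha ||b||_1 +
#' (1 - alpha) ||b||_2^2 / 2] with an unpenalized intercept, via glmnet.
#' Predictors are assumed pre-standardized (no internal rescaling). A
#' constant response has the analytic minimizer b = 0, b0 = mean(y), which
#' is returned directly.
#'
#' @param x samples x genes numeric matrix (pre-standardized columns).
#' @param y numeric response (nAUC), one value per sample.
#' @param alpha elastic-net mixing in (0, 1].
#' @param lambda penalty value (> 0 for a nontrivial fit).
#' @return list with `beta` (named coefficient vector) and `intercept`.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.5, lambda) {
  stop_if(nrow(x) != length(y), "dimension mismatch between x and y")
  stop_if(nrow(x) < 3, "need at least 3 samples")
  stop_if(any(!is.finite(x)) || any(!is.finite(y)), "non-finite values")
  if (sd(y) == 0) {
    beta <- setNames(numeric(ncol(x)), colnames(x))
    return(list(beta = beta, intercept = mean(y)))
  }
  p <- ncol(x)
  if (p == 1) {
    # glmnet needs >= 2 columns; pad with an all-zero column whose
    # coefficient is identically 0 under any penalty
    x <- cbind(x, `.pad` = 0)
  }
  # glmnet internally rescales the response to unit variance, which scales
  # the effective ridge term by 1/sd(y); refit on the unit-variance response
  # with a compensated (penalty, mixing) pair so the stated objective holds
  # exactly on the original scale
  sy <- sqrt(mean((y - mean(y))^2))
  z <- y / sy
  mu <- lambda * alpha / sy + lambda * (1 - alpha)
  a_hat <- if (mu > 0) (lambda * alpha / sy) / mu else alpha
  fit <- glmnet::glmnet(x, z, alpha = a_hat, standardize = FALSE,
                        intercept = TRUE, thresh = 1e-12)
  cf <- coef(fit, s = mu, exact = TRUE, x = x, y = z,
             alpha = a_hat, standardize = FALSE, intercept = TRUE,
             thresh = 1e-12)
  beta <- (sy * setNames(as.numeric(cf[-1]), colnames(x)))[seq_len(p)]
  list(beta = beta, intercept = sy * as.numeric(cf[1]))
}

#' Bootstrap elastic-net stability selection
#'
#' Resamples the samples (cell lines) with replacement B times, fits an
#' elastic net per resample with the configured penalty rule, and tallies
#' the sign of each gene's coefficient. The per-gene score is
#' max(freq_pos, freq_neg) - the frequency with which the gene enters the
#' model with a consistent sign - and genes scoring at or above the
#' threshold are marked selected. Degenerate resamples in which the response
#' has zero variance are redrawn (and counted). The per-gene Pearson
#' correlation with the phenotype is computed on the full, unresampled data.
#'
#' @param x samples x genes standardized matrix.
#' @param y phenotype vector (one mean nAUC per sample).
#' @param config list from [en_config()].
#' @return data frame (one row per gene): `gene`, `freq_pos`, `freq_neg`,
#'   `freq_zero`, `score`, `mean_coefficient`, `pearson_r`, `selected`;
#'   attribute `n_redrawn` counts degenerate resamples redrawn.
#' @export
bootstrap_stability <- function(x, y, config = en_config()) {
  n <- nrow(x)
  stop_if(n < 4, "need at least 4 samples to bootstrap")
  stop_if(length(y) != n, "dimension mismatch between x and y")
  p <- ncol(x)
  genes <- colnames(x)
  if (is.null(genes)) genes <- paste0("g", seq_len(p))

  res <- with_seed(config$seed, {
    pos <- neg <- numeric(p)
    coef_sum <- numeric(p)
    n_redrawn <- 0L
    for (b in seq_len(config$n_bootstrap)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(y[idx]) > 0) break
        n_redrawn <- n_redrawn + 1L
      }
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      beta <- if (is.null(config$lambda)) {
        cv <- glmnet::cv.glmnet(xb, yb, alpha = config$alpha,
                                nfolds = config$nfolds,
                                standardize = FALSE, intercept = TRUE,
                                grouped = FALSE)
        as.numeric(coef(cv, s = "lambda.min"))[-1]
      } else {
        fit_elastic_net(xb, yb, config$alpha, config$lambda)$beta
      }
      pos <- pos + (beta > 0)
      neg <- neg + (beta < 0)
      coef_sum <- coef_sum + beta
    }
    list(pos = pos, neg = neg, coef_sum = coef_sum, n_redrawn = n_redrawn)
  })

  freq_pos <- res$pos / config$n_bootstrap
  freq_neg <- res$neg / config$n_bootstrap
  score <- pmax(freq_pos, freq_neg)
  r <- apply(x, 2, function(g) if (sd(g) == 0) NA_real_ else cor(g, y))
  out <- data.frame(gene = genes, freq_pos = freq_pos, freq_neg = freq_neg,
                    freq_zero = 1 - freq_pos - freq_neg, score = score,
                    mean_coefficient = res$coef_sum / config$n_bootstrap,
                    pearson_r = r, selected = score >= config$score_threshold,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_redrawn") <- res$n_redrawn
  out
}

#' Retain genes above the stability score threshold
#'
#' Genes with score >= threshold (inclusive), ordered by score descending,
#' then |mean coefficient| descending, then gene identifier - a fully
#' deterministic ranking.
#'
#' @param table gene score table from [bootstrap_stability()].
#' @param threshold retention threshold in `[0, 1]`.
#' @return subset of `table`, ordered as described.
#' @export
select_genes <- function(table, threshold = 0.7) {
  stop_if(threshold < 0 || threshold > 1, "threshold must be in [0, 1]")
  keep <- table[table$score >= threshold, , drop = FALSE]
  keep[order(-keep$score, -abs(keep$mean_coefficient), keep$gene), ,
       drop = FALSE]
}

#' Pearson correlation between one gene and the phenotype
#'
#' @param x one gene's expression values.
#' @param y paired phenotype values.
#' @return Pearson product-moment correlation.
#' @export
gene_phenotype_correlation <- function(x, y) {
  stop_if(length(x) != length(y), "x and y lengths differ")
  stop_if(length(x) < 3, "need at least 3 paired values")
  stop_if(any(!is.finite(x)) || any(!is.finite(y)), "non-finite values")
  stop_if(sd(x) == 0 || sd(y) == 0, "zero variance")
  cor(x, y)
}
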