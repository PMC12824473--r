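#' Per-line dose-response phenotype parameters
#'
#' Parameterizes one cell line's surviving-fraction curve as an exponential
#' decay to a resistant plateau: V(A) = s + (1 - s) * exp(-k * A), where A is
#' the activity concentration (MBq/mL), `plateau` (s) is the surviving
#' fraction retained at arbitrarily high activity, and `rate` (k) controls how
#' fast viability falls with activity. This parametric family has a
#' closed-form normalized AUC, which downstream tests use as ground truth.
#'
#' @param line_id character identifier for the cell line.
#' @param plateau surviving fraction in `[0, 1]` at high activity
#'   (1 = fully resistant).
#' @param rate decay constant per (MBq/mL), `>= 0`.
#' @param noise_sd additive Gaussian noise SD on the fraction scale.
#' @param n_replicates number of independent replicates to simulate.
#' @return one-row data frame of validated parameters.
#' @export
line_phenotype_params <- function(line_id, plateau, rate,
                                  noise_sd = 0.05, n_replicates = 3) {
  stop_if(plateau < 0 || plateau > 1, "plateau must lie in [0, 1]")
  stop_if(rate < 0, "rate must be >= 0")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")
  stop_if(n_replicates < 1, "n_replicates must be a positive integer")
  data.frame(line_id = as.character(line_id), plateau = plateau, rate = rate,
             noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
             stringsAsFactors = FALSE)
}

#' Default activity ladder (MBq/mL)
#'
#' The eight activity concentrations used for the in-vitro microsphere
#' exposures, from untreated control to 20 MBq/mL.
#' @export
default_activities <- function() c(0, 0.1, 0.5, 1, 2, 4, 10, 20)

#' Simulate viability curves with known normalized AUC
#'
#' Draws surviving fractions V(A) = s + (1 - s) * exp(-k * A) + e,
#' e ~ Normal(0, noise_sd), truncated at 0, for each replicate of each line
#' over an activity ladder. The closed-form normalized AUC of the noiseless
#' curve, s + (1 - s) * (1 - exp(-k * A_max)) / (k * A_max) (with limit 1 as
#' k -> 0), is returned per line as ground truth.
#'
#' @param params data frame of per-line parameters; rows as produced by
#'   [line_phenotype_params()] (possibly `rbind`-ed).
#' @param activities ascending activity ladder starting at 0 (MBq/mL).
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with `viability` (tidy data frame: `cell_line`, `replicate`,
#'   `activity_mbq_per_ml`, `fraction`) and `true_nauc` (named numeric,
#'   closed-form normalized AUC per line).
#' @export
simulate_viability <- function(params, activities = default_activities(),
                               seed = 1L) {
  stop_if(length(activities) < 2, "need at least 2 activities")
  stop_if(any(activities < 0), "activities must be nonnegative")
  stop_if(is.unsorted(activities, strictly = TRUE),
          "activities must be strictly ascending")
  stop_if(activities[1] != 0, "first activity must be 0 (untreated control)")
  stop_if(anyDuplicated(params$line_id) > 0, "duplicate line_id in params")
  stop_if(any(params$plateau < 0 | params$plateau > 1) ||
            any(params$rate < 0) || any(params$noise_sd < 0),
          "invalid line parameters")

  a_max <- max(activities)
  rows <- with_seed(seed, {
    out <- vector("list", nrow(params))
    for (i in seq_len(nrow(params))) {
      p <- params[i, ]
      mu <- p$plateau + (1 - p$plateau) * exp(-p$rate * activities)
      reps <- lapply(seq_len(p$n_replicates), function(r) {
        frac <- pmax(0, mu + rnorm(length(activities), 0, p$noise_sd))
        data.frame(cell_line = p$line_id, replicate = r,
                   activity_mbq_per_ml = activities, fraction = frac,
                   stringsAsFactors = FALSE)
      })
      out[[i]] <- do.call(rbind, reps)
    }
    do.call(rbind, out)
  })
  true_nauc <- vapply(seq_len(nrow(params)), function(i) {
    closed_form_nauc(params$plateau[i], params$rate[i], a_max)
  }, numeric(1))
  names(true_nauc) <- params$line_id
  list(viability = rows, true_nauc = true_nauc)
}

#' Closed-form normalized AUC of the plateau-decay viability model
#'
#' For V(A) = s + (1 - s) * exp(-k * A) on `[0, a_max]`, the normalized AUC is
#' s + (1 - s) * (1 - exp(-k * a_max)) / (k * a_max); the k -> 0 limit is 1.
#'
#' @param plateau surviving fraction s in `[0, 1]`.
#' @param rate decay constant k `>= 0`.
#' @param a_max top of the activity ladder (MBq/mL), `> 0`.
#' @return normalized AUC in `[plateau, 1]`.
#' @export
closed_form_nauc <- function(plateau, rate, a_max) {
  stop_if(a_max <= 0, "a_max must be > 0")
  if (rate == 0) return(1)
  plateau + (1 - plateau) * (1 - exp(-rate * a_max)) / (rate * a_max)
}

#' Simulate a negative-binomial count matrix with planted phenotype genes
#'
#' Generates a genes x samples count matrix in which a planted subset of
#' genes varies linearly (on the natural-log mean scale) with a per-line
#' phenotype, emulating baseline RNA-seq across a cell-line panel. Gene
#' baselines are drawn Uniform(log 5, log 500); planted genes get slope
#' `effect` with a random sign, applied to the centered phenotype so the
#' planted perturbation stays compositionally small. Per-sample means are
#' rescaled so each library has expected size `depth`; counts are negative
#' binomial with the given dispersion (variance mu + dispersion * mu^2).
#'
#' @param n_genes number of genes.
#' @param phenotype named numeric, one finite value per line (e.g. nAUC).
#' @param planted number of phenotype-linked genes (`< n_genes`).
#' @param effect natural-log slope of the planted genes' mean per unit
#'   phenotype.
#' @param dispersion negative-binomial dispersion, `> 0`.
#' @param depth expected library size, `> 0`.
#' @param seed integer seed.
#' @return list with `counts` (genes x samples integer matrix), `planted`
#'   (data frame: `gene`, `sign`), `phenotype` (as given).
#' @export
simulate_expression <- function(n_genes, phenotype, planted, effect,
                                dispersion = 0.05, depth = 1e6, seed = 1L) {
  stop_if(planted >= n_genes, "planted must be < n_genes")
  stop_if(planted < 0, "planted must be >= 0")
  stop_if(any(!is.finite(phenotype)), "phenotype values must be finite")
  stop_if(is.null(names(phenotype)), "phenotype must be named by line")
  stop_if(depth <= 0, "depth must be > 0")
  stop_if(dispersion <= 0, "dispersion must be > 0")

  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    baseline <- runif(n_genes, log(5), log(500))
    idx <- if (planted > 0) sample.int(n_genes, planted) else integer(0)
    signs <- if (planted > 0) sample(c(-1, 1), planted, replace = TRUE)
             else numeric(0)
    slope <- numeric(n_genes)
    slope[idx] <- signs * effect
    # log-mean = baseline_g + slope_g * (phenotype - mean); centering keeps
    # planted genes a small symmetric perturbation of the library rather
    # than letting them dominate composition at one end of the phenotype
    lmu <- outer(baseline, rep(1, length(phenotype))) +
      outer(slope, phenotype - mean(phenotype))
    mu <- exp(lmu)
    mu <- sweep(mu, 2, colSums(mu) / depth, "/")
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_genes,
                     dimnames = list(genes, names(phenotype)))
    list(counts = counts,
         planted = data.frame(gene = genes[idx], sign = signs,
                              stringsAsFactors = FALSE),
         phenotype = phenotype)
  })
}

#' Simulate marker-signature profiles with known class labels
#'
#' Builds a test bed for nearest-template classification: each class owns
#' `markers_per_class` marker genes; a sample of class c is the class
#' template (+1 on its own markers, -1 on all other classes' markers) plus
#' Gaussian noise.
#'
#' @param classes character vector of `>= 2` class names.
#' @param markers_per_class markers owned by each class (`>= 1`).
#' @param n_samples_per_class samples simulated per class.
#' @param noise_sd Gaussian noise SD added to each profile entry.
#' @param seed integer seed.
#' @return list with `profiles` (genes x samples matrix), `signature`
#'   (named list class -> marker genes, GMT-ready), `labels` (named character,
#'   true class per sample), `templates` (genes x classes, un-normalized
#'   +1/-1 pattern).
#' @export
simulate_signature_profiles <- function(classes, markers_per_class = 20,
                                        n_samples_per_class = 5,
                                        noise_sd = 0.5, seed = 1L) {
  stop_if(length(classes) < 2, "need at least 2 classes")
  stop_if(markers_per_class < 1, "markers_per_class must be >= 1")
  stop_if(n_samples_per_class < 1, "n_samples_per_class must be >= 1")
  stop_if(noise_sd < 0, "noise_sd must be >= 0")

  genes <- unlist(lapply(classes, function(cl)
    sprintf("%s.M%02d", cl, seq_len(markers_per_class))))
  owner <- rep(classes, each = markers_per_class)
  templates <- vapply(classes, function(cl) ifelse(owner == cl, 1, -1),
                      numeric(length(genes)))
  rownames(templates) <- genes

  samples <- unlist(lapply(classes, function(cl)
    sprintf("%s.S%02d", cl, seq_len(n_samples_per_class))))
  labels <- setNames(rep(classes, each = n_samples_per_class), samples)

  profiles <- with_seed(seed, {
    m <- templates[, labels, drop = FALSE] +
      matrix(rnorm(length(genes) * length(samples), 0, noise_sd),
             nrow = length(genes))
    dimnames(m) <- list(genes, samples)
    m
  })
  signature <- split(genes, owner)[classes]
  list(profiles = profiles, signature = signature, labels = labels,
       templates = templates)
}

#' Default 10-line synthetic cohort parameters
#'
#' A panel of ten synthetic liver-cancer-like lines spanning resistant
#' (high plateau) to sensitive (low plateau, fast decay) phenotypes, with
#' triplicate viability measurements and moderate replicate noise.
#' @export
default_cohort_params <- function() {
  do.call(rbind, list(
    line_phenotype_params("L01", 0.90, 2.0),
    line_phenotype_params("L02", 0.85, 1.5),
    line_phenotype_params("L03", 0.80, 1.0),
    line_phenotype_params("L04", 0.75, 0.8),
    line_phenotype_params("L05", 0.70, 0.8),
    line_phenotype_params("L06", 0.65, 0.6),
    line_phenotype_params("L07", 0.60, 0.6),
    line_phenotype_params("L08", 0.55, 0.5),
    line_phenotype_params("L09", 0.50, 0.5),
    line_phenotype_params("L10", 0.30, 0.4)
  ))
}

#' Simulate a complete cohort: viability, expression, signatures, truth
#'
#' Convenience wrapper tying the three generators together so every pipeline
#' stage can run against data with known ground truth. Expression phenotype
#' is the closed-form normalized AUC of each line's noiseless curve.
#'
#' @param params per-line viability parameters (default ten-line panel).
#' @param activities activity ladder (MBq/mL).
#' @param n_genes,planted,effect,dispersion,depth passed to
#'   [simulate_expression()].
#' @param classes,markers_per_class,noise_sd passed to
#'   [simulate_signature_profiles()] (one signature sample per line is
#'   attached by relabeling columns to line ids).
#' @param seed integer master seed; sub-seeds are derived per component.
#' @return list with `viability`, `true_nauc`, `expression` (counts + truth),
#'   `signatures` (profiles, signature, labels), `seed`.
#' @export
simulate_cohort <- function(params = default_cohort_params(),
                            activities = default_activities(),
                            n_genes = 500, planted = 5, effect = 6,
                            dispersion = 0.05, depth = 1e6,
                            classes = c("S1", "S2", "S3"),
                            markers_per_class = 20, noise_sd = 0.5,
                            seed = 1L) {
  viab <- simulate_viability(params, activities, seed = derive_seed(seed, 1))
  expr <- simulate_expression(n_genes, viab$true_nauc, planted, effect,
                              dispersion, depth,
                              seed = derive_seed(seed, 2))
  n_lines <- nrow(params)
  per_class <- ceiling(n_lines / length(classes))
  sig <- simulate_signature_profiles(classes, markers_per_class,
                                     n_samples_per_class = per_class,
                                     noise_sd = noise_sd,
                                     seed = derive_seed(seed, 3))
  keep <- seq_len(n_lines)
  sig$profiles <- sig$profiles[, keep, drop = FALSE]
  sig$labels <- sig$labels[keep]
  colnames(sig$profiles) <- names(sig$labels) <- params$line_id
  list(viability = viab$viability, true_nauc = viab$true_nauc,
       expression = expr, signatures = sig, seed = seed)
}
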