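#' log-CPM transform of a count matrix
#'
#' Maps raw counts to log2 counts-per-million with small offsets,
#' log2((count + 0.5) / (library_size + 1) * 1e6), producing the
#' microarray-like scale used for template matching. No precision weighting
#' is applied: this is a plain log-CPM surrogate for a variance-modeled
#' transform, and is documented as such.
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @return matrix of log2-CPM values, same dimensions.
#' @export
logcpm_transform <- function(counts) {
  stop_if(any(counts < 0), "counts must be nonnegative")
  lib <- colSums(counts)
  stop_if(any(lib == 0), "zero library size in column(s): ",
          paste(which(lib == 0), collapse = ", "))
  t(log2(t(counts + 0.5) / (lib + 1) * 1e6))
}

#' Construct a marker signature set
#'
#' A signature maps each marker gene to exactly one class with a direction
#' (+1 up in that class, -1 down). Plain lists of up-regulated markers per
#' class are the common case.
#'
#' @param markers named list: class -> character vector of marker genes; or
#'   a data frame with columns `gene`, `class`, `direction`.
#' @return data frame with columns `gene`, `class`, `direction`.
#' @export
signature_set <- function(markers) {
  if (is.data.frame(markers)) {
    stop_if(!all(c("gene", "class") %in% names(markers)),
            "data frame signature needs gene and class columns")
    if (is.null(markers$direction)) markers$direction <- 1
    sig <- markers[, c("gene", "class", "direction")]
  } else {
    stop_if(is.null(names(markers)), "marker list must be named by class")
    stop_if(any(lengths(markers) < 1),
            "every class needs >= 1 marker; empty class: ",
            paste(names(markers)[lengths(markers) < 1], collapse = ", "))
    sig <- data.frame(
      gene = unlist(markers, use.names = FALSE),
      class = rep(names(markers), lengths(markers)),
      direction = 1, stringsAsFactors = FALSE)
  }
  stop_if(length(unique(sig$class)) < 1, "signature has no classes")
  stop_if(any(table(sig$class) < 1), "every class needs >= 1 marker")
  stop_if(anyDuplicated(sig$gene) > 0,
          "each gene must map to exactly one class")
  stop_if(!all(sig$direction %in% c(-1, 1)), "directions must be +1 or -1")
  sig
}

#' Build unit-norm class templates over the marker universe
#'
#' For class c, the template takes value +direction on genes that are
#' markers of c and -direction on every other marker gene, then is scaled to
#' unit Euclidean norm. Samples are compared to these templates by cosine
#' distance.
#'
#' @param signature signature from [signature_set()] (or input acceptable to
#'   it).
#' @return marker-genes x classes matrix of unit-norm templates.
#' @export
build_templates <- function(signature) {
  sig <- signature_set(signature)
  classes <- unique(sig$class)
  tmpl <- matrix(vapply(classes, function(cl) {
    v <- ifelse(sig$class == cl, sig$direction, -sig$direction)
    v / sqrt(sum(v^2))
  }, numeric(nrow(sig))), nrow = nrow(sig),
  dimnames = list(sig$gene, classes))
  tmpl
}

#' Nearest template prediction with a permutation null
#'
#' Assigns each sample to the class whose template is nearest in cosine
#' distance (d = 1 - cosine similarity) over the marker genes present in the
#' profile. Significance comes from a permutation null: marker labels are
#' permuted over the profile's genes n_perm times, the minimum distance
#' across all class templates is recomputed for each permutation, and
#' p = (1 + #{null minima <= observed minimum}) / (1 + n_perm). Taking the
#' minimum over all templates in the null matches the observed statistic, so
#' null p-values are uniform by exchangeability. Benjamini-Hochberg FDR is
#' computed across samples. Ties in the nearest class are broken by class
#' order and flagged.
#'
#' @param profiles marker-space expression: genes x samples matrix (or a
#'   named vector for a single sample). Genes absent from the signature are
#'   ignored.
#' @param signature signature acceptable to [signature_set()].
#' @param n_perm number of label permutations (>= 1).
#' @param seed integer seed for the permutation draws.
#' @return data frame: `sample`, `class`, `distance`, `p_value`, `fdr`,
#'   `n_permutations`, `tie`.
#' @export
ntp_classify <- function(profiles, signature, n_perm = 1000, seed = 1L) {
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, ncol = 1,
                       dimnames = list(names(profiles), "sample1"))
  stop_if(n_perm < 1, "n_perm must be >= 1")
  tmpl <- build_templates(signature)
  classes <- colnames(tmpl)
  common <- intersect(rownames(tmpl), rownames(profiles))
  stop_if(length(common) < 2,
          "fewer than 2 marker genes present in the profiles")
  tmpl <- tmpl[common, , drop = FALSE]
  # renormalize templates over the genes actually present
  tmpl <- sweep(tmpl, 2, sqrt(colSums(tmpl^2)), "/")
  x <- profiles[common, , drop = FALSE]
  m <- length(common)

  perm_idx <- with_seed(seed, {
    t(vapply(seq_len(n_perm), function(i) sample.int(m), integer(m)))
  })

  rows <- lapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    stop_if(sd(v) == 0, "profile ", colnames(x)[j], " has zero variance")
    u <- v / sqrt(sum(v^2))
    d <- 1 - as.numeric(crossprod(u, tmpl))        # cosine distances
    best <- which.min(d)
    tie <- sum(d == d[best]) > 1
    # null: permute marker labels over the genes, min distance over classes
    perm_mat <- matrix(u[t(perm_idx)], nrow = m)   # m x n_perm
    null_min <- 1 - apply(crossprod(perm_mat, tmpl), 1, max)
    # ties with the observed distance count as at-least-as-extreme; the
    # tolerance absorbs floating-point noise between equal permuted values
    p <- (1 + sum(null_min <= d[best] + 1e-9)) / (1 + n_perm)
    data.frame(sample = colnames(x)[j], class = classes[best],
               distance = d[best], p_value = p,
               n_permutations = n_perm, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out[, c("sample", "class", "distance", "p_value", "fdr",
          "n_permutations", "tie")]
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment; monotone, adjusted >= raw, capped at 1.
#'
#' @param p p-values in `[0, 1]`.
#' @return adjusted values, same length.
#' @export
bh_fdr <- function(p) {
  stop_if(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Test subtype vs phenotype association (Kruskal-Wallis)
#'
#' Rank-based Kruskal-Wallis test of whether the phenotype (mean nAUC per
#' line) differs across assigned subtype classes, with tie correction. When
#' every observation is tied the statistic is defined as 0 (p = 1).
#'
#' @param labels class label per line.
#' @param values numeric phenotype per line, same length.
#' @return list with `h` (H statistic), `p` (chi-square p, k - 1 df), `df`.
#' @export
subtype_phenotype_association <- function(labels, values) {
  stop_if(length(labels) != length(values), "labels/values length mismatch")
  labels <- factor(labels)
  stop_if(nlevels(labels) < 2, "need at least 2 classes")
  if (length(unique(values)) == 1)
    return(list(h = 0, p = 1, df = nlevels(labels) - 1))
  kt <- kruskal.test(values, labels)
  list(h = as.numeric(kt$statistic), p = kt$p.value,
       df = as.numeric(kt$parameter))
}
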