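#' Gene-wise two-group differential expression (Welch test on log scale)
#'
#' A transparent surrogate differential-expression stage: per gene, a Welch
#' two-sample t-test on log-scale values between two groups, with the log2
#' fold change defined as mean(group B) - mean(group A) and
#' Benjamini-Hochberg adjustment across genes. This is deliberately NOT a
#' count-model (negative-binomial) DE fit; it is a simple location test whose
#' downstream significance-filter and gene-set summaries are the quantities
#' of interest. Genes with zero variance in both groups get p = 1 and are
#' flagged.
#'
#' @param logexpr genes x samples matrix on the log2 scale.
#' @param groups two-level factor/character per sample; the first level is
#'   group A (reference), the second group B.
#' @return data frame per gene: `gene`, `mean_a`, `mean_b`, `log2fc`, `p`,
#'   `q`, `zero_variance`.
#' @export
gene_wise_de <- function(logexpr, groups) {
  groups <- factor(groups)
  stop_if(nlevels(groups) != 2, "groups must have exactly 2 levels")
  stop_if(ncol(logexpr) != length(groups), "sample/label length mismatch")
  na <- sum(groups == levels(groups)[1])
  nb <- sum(groups == levels(groups)[2])
  stop_if(na < 2 || nb < 2, "each group needs >= 2 samples")

  xa <- logexpr[, groups == levels(groups)[1], drop = FALSE]
  xb <- logexpr[, groups == levels(groups)[2], drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1, var); vb <- apply(xb, 1, var)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  zero_var <- se2 == 0
  p[zero_var] <- 1
  genes <- rownames(logexpr)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(logexpr)))
  data.frame(gene = genes, mean_a = ma, mean_b = mb, log2fc = mb - ma,
             p = p, q = bh_fdr(p), zero_variance = zero_var,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter differential-expression results by FDR and fold change
#'
#' Keeps rows with q strictly below `q_max` and |log2fc| strictly above
#' `lfc_min` (FDR < 0.05 and |log2 FC| > 2 by default; the fold-change
#' threshold is applied two-sidedly).
#'
#' @param table data frame from [gene_wise_de()].
#' @param q_max FDR ceiling (exclusive), > 0.
#' @param lfc_min absolute log2 fold-change floor (exclusive), > 0.
#' @return the significant subset (possibly empty).
#' @export
filter_significant <- function(table, q_max = 0.05, lfc_min = 2) {
  stop_if(q_max <= 0 || lfc_min <= 0, "thresholds must be positive")
  table[table$q < q_max & abs(table$log2fc) > lfc_min, , drop = FALSE]
}

#' Mean log2 fold change of a gene set
#'
#' Arithmetic mean of log2 fold changes over the set members present in the
#' result table (all present members, not only significant ones).
#'
#' @param table data frame from [gene_wise_de()].
#' @param gene_set character vector of gene identifiers.
#' @param set_name label used in error messages and output.
#' @return list: `set`, `n_set`, `n_present`, `mean_lfc`.
#' @export
pathway_mean_lfc <- function(table, gene_set, set_name = "gene_set") {
  present <- intersect(gene_set, table$gene)
  stop_if(length(present) == 0,
          "no members of set '", set_name, "' present in the table")
  list(set = set_name, n_set = length(gene_set),
       n_present = length(present),
       mean_lfc = mean(table$log2fc[match(present, table$gene)]))
}

#' Mean log2 fold change for every set in a collection
#'
#' @param table data frame from [gene_wise_de()].
#' @param sets named list: set name -> gene identifiers (e.g. from
#'   [read_gmt()]). Sets with no member present are reported with
#'   `n_present = 0` and `mean_lfc = NA` rather than erroring.
#' @return data frame: `set`, `n_set`, `n_present`, `mean_lfc`.
#' @export
pathway_mean_lfc_table <- function(table, sets) {
  stop_if(is.null(names(sets)), "sets must be a named list")
  rows <- lapply(names(sets), function(nm) {
    present <- intersect(sets[[nm]], table$gene)
    data.frame(set = nm, n_set = length(sets[[nm]]),
               n_present = length(present),
               mean_lfc = if (length(present))
                 mean(table$log2fc[match(present, table$gene)]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
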