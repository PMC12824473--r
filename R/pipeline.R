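#' Pipeline run configuration
#'
#' One declarative configuration for the whole analysis: input file paths
#' (or `NULL` to simulate a cohort with known ground truth), grouping
#' thresholds, elastic-net settings, template-classification settings,
#' differential-expression thresholds, the master seed, and the output
#' directory. Each stage derives its own sub-seed from the master seed so
#' stages re-run independently yet reproducibly.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master integer seed; recorded in every output header.
#' @param viability_file,expression_file,signature_file input paths; leave
#'   `NULL` to generate a synthetic cohort instead.
#' @param resistant_z,sensitive_z grouping thresholds on the nAUC Z-score.
#' @param en [en_config()] settings for stability selection.
#' @param n_perm permutations for template classification.
#' @param q_max,lfc_min differential-expression significance thresholds.
#' @param stages subset of
#'   `c("simulate", "nauc", "select", "classify", "de")` to run; stages with
#'   unmet dependencies are skipped with a warning.
#' @return validated configuration list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       viability_file = NULL, expression_file = NULL,
                       signature_file = NULL,
                       resistant_z = 0, sensitive_z = -0.45,
                       en = en_config(seed = derive_seed(seed, 30)),
                       n_perm = 1000, q_max = 0.05, lfc_min = 2,
                       stages = c("simulate", "nauc", "select", "classify",
                                  "de")) {
  for (f in c(viability_file, expression_file, signature_file))
    stop_if(!file.exists(f), "input file not found: ", f)
  list(out_dir = out_dir, seed = as.integer(seed),
       viability_file = viability_file, expression_file = expression_file,
       signature_file = signature_file, resistant_z = resistant_z,
       sensitive_z = sensitive_z, en = en, n_perm = n_perm,
       q_max = q_max, lfc_min = lfc_min, stages = stages)
}

#' Validate pipeline input files
#'
#' Schema checks for the three input formats: the viability CSV (required
#' columns, activity-0 control per line/replicate), the expression TSV
#' (parseable numeric matrix), and the GMT signature (every line has at
#' least 3 tab-separated fields). Problems are split into errors and
#' warnings.
#'
#' @param viability_file,expression_file,signature_file paths (each may be
#'   `NULL` to skip).
#' @return list with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(viability_file = NULL, expression_file = NULL,
                            signature_file = NULL) {
  errors <- character(0)
  warnings <- character(0)
  if (!is.null(viability_file)) {
    if (!file.exists(viability_file)) {
      errors <- c(errors, paste0("unreadable file: ", viability_file))
    } else {
      v <- tryCatch(read_viability_csv(viability_file), error = function(e) e)
      if (inherits(v, "error")) {
        errors <- c(errors, paste0("viability CSV parse failure: ",
                                   conditionMessage(v)))
      } else {
        need <- c("cell_line", "replicate", "activity_mbq_per_ml")
        miss <- setdiff(need, names(v))
        if (length(miss)) {
          errors <- c(errors, paste0("viability CSV missing column(s): ",
                                     paste(miss, collapse = ", ")))
        } else {
          key <- interaction(v$cell_line, v$replicate, drop = TRUE)
          has0 <- tapply(v$activity_mbq_per_ml, key, function(a) any(a == 0))
          if (!all(has0))
            errors <- c(errors, paste0(
              "no activity-0 control for: ",
              paste(names(has0)[!has0], collapse = ", ")))
        }
      }
    }
  }
  if (!is.null(expression_file)) {
    if (!file.exists(expression_file)) {
      errors <- c(errors, paste0("unreadable file: ", expression_file))
    } else {
      m <- tryCatch(read_expression_tsv(expression_file),
                    error = function(e) e)
      if (inherits(m, "error"))
        errors <- c(errors, paste0("expression TSV parse failure: ",
                                   conditionMessage(m)))
      else if (anyNA(m))
        warnings <- c(warnings, "expression matrix contains missing values")
    }
  }
  if (!is.null(signature_file)) {
    if (!file.exists(signature_file)) {
      errors <- c(errors, paste0("unreadable file: ", signature_file))
    } else {
      lines <- readLines(signature_file)
      nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
      bad <- which(nf < 3)
      if (length(bad))
        errors <- c(errors, paste0("GMT line(s) with fewer than 3 fields: ",
                                   paste(bad, collapse = ", ")))
    }
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> nAUC phenotyping -> grouping ->
#' bootstrap elastic-net selection -> template classification -> two-group
#' differential expression with gene-set summaries, writing every artifact
#' as TSV/CSV/GMT/JSON under the configured output directory, and finally a
#' JSON manifest listing each artifact with its MD5 content hash, the seeds
#' used, and the package version. Any stage failure aborts with the stage
#' name. Expression samples must cover every viability line; a missing line
#' is a hard error naming it.
#'
#' @param config list from [run_config()].
#' @return the manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  meta <- c(seed = config$seed)
  emit <- function(df, name, extra = NULL) {
    p <- file.path(config$out_dir, name)
    write_tsv_meta(df, p, meta = c(meta, extra))
    paths[[name]] <<- p
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth <- NULL
  signature <- NULL
  sig_profiles <- NULL

  if ("simulate" %in% config$stages && is.null(config$viability_file)) {
    cohort <- stage("simulate", simulate_cohort(seed = config$seed))
    viability <- cohort$viability
    counts <- cohort$expression$counts
    truth <- cohort
    signature <- cohort$signatures$signature
    sig_profiles <- cohort$signatures$profiles
    p <- file.path(config$out_dir, "viability.csv")
    write_viability_csv(viability, p); paths[["viability.csv"]] <- p
    p <- file.path(config$out_dir, "expression_counts.tsv")
    write_expression_tsv(counts, p); paths[["expression_counts.tsv"]] <- p
    p <- file.path(config$out_dir, "signature.gmt")
    write_gmt(signature, p); paths[["signature.gmt"]] <- p
    p <- file.path(config$out_dir, "truth.json")
    jsonlite::write_json(list(true_nauc = as.list(cohort$true_nauc),
                              planted_genes = cohort$expression$planted$gene,
                              true_labels = as.list(cohort$signatures$labels),
                              seed = config$seed),
                         p, auto_unbox = TRUE, digits = NA)
    paths[["truth.json"]] <- p
  } else {
    viability <- stage("load", {
      stop_if(is.null(config$viability_file), "no viability input")
      read_viability_csv(config$viability_file)
    })
    counts <- if (!is.null(config$expression_file))
      read_expression_tsv(config$expression_file) else NULL
    if (!is.null(config$signature_file))
      signature <- read_gmt(config$signature_file)
  }

  if (!is.null(counts)) {
    missing <- setdiff(unique(viability$cell_line), colnames(counts))
    stop_if(length(missing) > 0,
            "expression matrix lacks viability line(s): ",
            paste(missing, collapse = ", "))
  }

  profile <- NULL
  if ("nauc" %in% config$stages) {
    profile <- stage("nauc", {
      reps <- compute_replicate_nauc(viability)
      emit(reps, "nauc_replicates.tsv")
      smry <- summarize_nauc(reps)
      grouped <- assign_groups(smry, config$resistant_z, config$sensitive_z)
      emit(grouped, "nauc_profile.tsv",
           extra = c(resistant_z = config$resistant_z,
                     sensitive_z = config$sensitive_z))
      av <- compare_lines_anova(reps$nauc, reps$cell_line)
      p <- file.path(config$out_dir, "anova.json")
      jsonlite::write_json(list(f = av$f, p = av$p,
                                df_between = av$df_between,
                                df_within = av$df_within, seed = config$seed),
                           p, auto_unbox = TRUE, digits = NA)
      paths[["anova.json"]] <- p
      grouped
    })
  }

  logexpr <- if (!is.null(counts)) logcpm_transform(counts) else NULL

  if ("select" %in% config$stages && !is.null(logexpr) &&
      !is.null(profile)) {
    stage("select", {
      x <- t(suppressWarnings(standardize_expression(logexpr)))
      y <- profile$mean_nauc[match(rownames(x), profile$cell_line)]
      stop_if(anyNA(y), "phenotype missing for some expression samples")
      scores <- bootstrap_stability(x, y, config$en)
      emit(scores, "gene_scores.tsv",
           extra = c(n_bootstrap = config$en$n_bootstrap,
                     alpha = config$en$alpha))
      emit(select_genes(scores, config$en$score_threshold),
           "selected_genes.tsv",
           extra = c(threshold = config$en$score_threshold))
    })
  }

  if ("classify" %in% config$stages && !is.null(signature)) {
    stage("classify", {
      prof <- if (!is.null(sig_profiles)) sig_profiles else logexpr
      stop_if(is.null(prof), "no profiles available for classification")
      calls <- ntp_classify(prof, signature, n_perm = config$n_perm,
                            seed = derive_seed(config$seed, 40))
      emit(calls, "subtype_calls.tsv",
           extra = c(n_perm = config$n_perm))
      if (!is.null(profile)) {
        common <- intersect(calls$sample, profile$cell_line)
        if (length(unique(calls$class[match(common, calls$sample)])) >= 2) {
          kw <- subtype_phenotype_association(
            calls$class[match(common, calls$sample)],
            profile$mean_nauc[match(common, profile$cell_line)])
          p <- file.path(config$out_dir, "subtype_association.json")
          jsonlite::write_json(kw, p, auto_unbox = TRUE, digits = NA)
          paths[["subtype_association.json"]] <- p
        }
      }
    })
  }

  if ("de" %in% config$stages && !is.null(logexpr) && !is.null(profile)) {
    stage("de", {
      grp <- profile$group[match(colnames(logexpr), profile$cell_line)]
      keep <- grp %in% c("sensitive", "resistant")
      if (sum(grp[keep] == "sensitive") >= 2 &&
          sum(grp[keep] == "resistant") >= 2) {
        de <- gene_wise_de(logexpr[, keep, drop = FALSE],
                           factor(grp[keep],
                                  levels = c("sensitive", "resistant")))
        emit(de, "de_results.tsv")
        emit(filter_significant(de, config$q_max, config$lfc_min),
             "de_significant.tsv",
             extra = c(q_max = config$q_max, lfc_min = config$lfc_min))
        sets <- list()
        if (!is.null(truth))
          sets$planted <- truth$expression$planted$gene
        if (!is.null(signature)) sets <- c(sets, signature)
        if (length(sets))
          emit(pathway_mean_lfc_table(de, sets), "set_summary.tsv")
      } else {
        warning("fewer than 2 samples in a DE group; stage skipped",
                call. = FALSE)
      }
    })
  }

  manifest <- list(
    package = "y90profiler",
    version = as.character(packageVersion("y90profiler")),
    seed = config$seed,
    stages = config$stages,
    artifacts = lapply(names(paths), function(nm)
      list(name = nm, path = paths[[nm]],
           md5 = unname(tools::md5sum(paths[[nm]]))))
  )
  mp <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
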