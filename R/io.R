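# File-based front end. Matrices travel as TSV (first column = feature/gene
# id, header row = sample ids), structured reports as JSON. Every output
# file opens with a comment line carrying a hash of the run configuration,
# so identical configurations are recognizable and reruns are byte-identical.

#' Read an expression (or activity) TSV
#'
#' First column: gene/feature id; header row: sample ids; `#` lines are
#' comments. Gzip-compressed files are read transparently.
#'
#' @param path File path.
#' @return Numeric matrix with row and column names.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "double"
  check_expression_matrix(m)
  m
}

#' Write a feature x sample matrix as TSV
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_column Name of the first column.
#' @param comments Character vector written as leading `#` lines.
#' @export
write_matrix_tsv <- function(m, path, id_column = "feature",
                             comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_column, colnames(m)), collapse = "\t"), con)
  write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE,
              row.names = TRUE)
  invisible(path)
}

#' Read a two-group design TSV
#'
#' Columns `sample` and `group`.
#'
#' @param path File path.
#' @param reference Optional reference group label.
#' @return A [group_design()].
#' @export
read_design_tsv <- function(path, reference = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample", "group") %in% names(df))) {
    stop("design TSV '", path, "' needs columns sample, group")
  }
  group_design(df$sample, df$group, reference = reference)
}

run_config <- function(...) {
  cfg <- list(...)
  files <- cfg[grepl("_file$|_files$", names(cfg))]
  for (f in unlist(files)) {
    if (!is.null(f) && !file.exists(f)) stop("input file not found: ", f)
  }
  cfg
}

write_provenance <- function(output_dir, cfg) {
  prov <- list(package = "pathflow",
               version = as.character(utils::packageVersion("pathflow")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               config = cfg[!vapply(cfg, is.null, logical(1))],
               config_hash = config_hash(cfg))
  path <- file.path(output_dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  path
}

# Run `expr`, removing any files it created under output_dir on error.
with_clean_outputs <- function(output_dir, expr) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  before <- list.files(output_dir, full.names = TRUE)
  tryCatch(expr, error = function(e) {
    created <- setdiff(list.files(output_dir, full.names = TRUE), before)
    unlink(created)
    stop(e)
  })
}

load_pathway_files <- function(pathway_files, dialect) {
  as_pathway_list(lapply(pathway_files, load_pathway, dialect = dialect))
}

#' Compute and write activity matrices (pipeline subcommand `activity`)
#'
#' Writes `circuit_activity.tsv`, `effector_activity.tsv`, optionally
#' `function_activity.tsv`, a feature-metadata TSV per circuit level, and a
#' `provenance.json` with package versions and a configuration hash. On
#' error, partial outputs are removed.
#'
#' @param pathway_files Character vector of pathway file paths.
#' @param expression_file Expression TSV path.
#' @param output_dir Output directory (created if needed).
#' @param dialect Pathway dialect, see [load_pathway()].
#' @param annotation_file Optional GMT file for the function level.
#' @param variant_file Optional VCF/TSV of variant calls ([read_variant_calls()]).
#' @param inheritance Inheritance mode for variant integration.
#' @param scale,truncation_quantile Passed to [circuit_activity()].
#' @param cfg A [propagation_config()].
#' @return Invisibly, the vector of files written.
#' @export
run_activity <- function(pathway_files, expression_file, output_dir,
                         dialect = "native_json", annotation_file = NULL,
                         variant_file = NULL, inheritance = "dominant",
                         scale = TRUE, truncation_quantile = 0.99,
                         cfg = propagation_config()) {
  config <- run_config(pathway_files = pathway_files,
                       expression_file = expression_file,
                       annotation_file = annotation_file,
                       variant_file = variant_file,
                       dialect = dialect, inheritance = inheritance,
                       scale = scale,
                       truncation_quantile = truncation_quantile,
                       convergence_threshold = cfg$convergence_threshold,
                       max_passes = cfg$max_passes)
  hash <- config_hash(config)
  with_clean_outputs(output_dir, {
    pathways <- load_pathway_files(pathway_files, dialect)
    expr <- read_expression_tsv(expression_file)
    ann <- if (!is.null(annotation_file)) {
      load_function_annotations(annotation_file)
    }
    integrity <- if (!is.null(variant_file)) {
      calls <- read_variant_calls(variant_file)
      compute_integrity(calls, genes = rownames(expr),
                        samples = colnames(expr),
                        inheritance = inheritance)
    }
    res <- circuit_activity(pathways, expr, annotations = ann,
                            integrity = integrity, scale = scale,
                            truncation_quantile = truncation_quantile,
                            cfg = cfg)
    comments <- paste0("config_hash: ", hash)
    written <- c(
      write_matrix_tsv(res$circuit,
                       file.path(output_dir, "circuit_activity.tsv"),
                       comments = comments),
      write_matrix_tsv(res$effector,
                       file.path(output_dir, "effector_activity.tsv"),
                       comments = comments))
    meta <- rbind(activity_metadata(res$circuit),
                  activity_metadata(res$effector))
    meta_path <- file.path(output_dir, "circuit_metadata.tsv")
    con <- file(meta_path, "w")
    writeLines(paste0("# ", comments), con)
    write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    written <- c(written, meta_path)
    if (!is.null(res$functions)) {
      written <- c(written,
                   write_matrix_tsv(res$functions,
                                    file.path(output_dir,
                                              "function_activity.tsv"),
                                    comments = comments))
    }
    written <- c(written, write_provenance(output_dir, config))
    invisible(written)
  })
}

#' Differential activation from an activity TSV (subcommand `compare`)
#'
#' @param activity_file Activity TSV (as written by [run_activity()]).
#' @param design_file Design TSV (`sample`, `group`).
#' @param output_dir Output directory.
#' @param reference Optional reference group label.
#' @param threshold FDR threshold echoed into the significant-feature list.
#' @return Invisibly, the files written.
#' @export
run_compare <- function(activity_file, design_file, output_dir,
                        reference = NULL, threshold = 0.05) {
  config <- run_config(activity_file = activity_file,
                       design_file = design_file, reference = reference,
                       threshold = threshold)
  with_clean_outputs(output_dir, {
    acts <- read_expression_tsv(activity_file)
    design <- read_design_tsv(design_file, reference = reference)
    res <- compare_groups(acts, design)
    out <- file.path(output_dir, "differential.tsv")
    con <- file(out, "w")
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
    write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    sig <- file.path(output_dir, "significant.txt")
    writeLines(significant_features(res, threshold), sig)
    invisible(c(out, sig, write_provenance(output_dir, config)))
  })
}

#' Survival scan from an activity TSV (subcommand `survival`)
#'
#' @param activity_file Activity TSV.
#' @param survival_file Survival TSV (`sample`, `time`, `event`).
#' @param output_dir Output directory.
#' @param fraction Extreme fraction, see [survival_scan()].
#' @return Invisibly, the files written.
#' @export
run_survival <- function(activity_file, survival_file, output_dir,
                         fraction = 0.1) {
  config <- run_config(activity_file = activity_file,
                       survival_file = survival_file, fraction = fraction)
  with_clean_outputs(output_dir, {
    acts <- read_expression_tsv(activity_file)
    surv <- read_survival_tsv(survival_file)
    res <- survival_scan(acts, surv, fraction = fraction)
    out <- file.path(output_dir, "survival_scan.tsv")
    con <- file(out, "w")
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
    write.table(res, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    invisible(c(out, write_provenance(output_dir, config)))
  })
}

#' Specificity benchmark on synthetic pathways (subcommand `simulate-fpr`)
#'
#' Generates `n_pathways` synthetic pathways (the last one containing
#' feedback when `with_loop`), runs [estimate_fpr()] under the flat-normal
#' scenario and writes the report as JSON plus the per-repetition fractions
#' as TSV.
#'
#' @param output_dir Output directory.
#' @param n_pathways,n_nodes Synthetic pathway count and size.
#' @param with_loop Give the last pathway feedback edges.
#' @param inhibition_fraction Inhibition edge fraction.
#' @param n_genes Gene universe size.
#' @param n_samples Cohort size (even).
#' @param repetitions,alpha,seed See [estimate_fpr()].
#' @return Invisibly, the `ccaa_benchmark` report.
#' @export
run_simulate_fpr <- function(output_dir, n_pathways = 3L, n_nodes = 15L,
                             with_loop = TRUE, inhibition_fraction = 0.2,
                             n_genes = 1000L, n_samples = 40L,
                             repetitions = 100L, alpha = 0.05, seed = 1L) {
  config <- as.list(environment())
  with_clean_outputs(output_dir, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    pathways <- lapply(seq_len(n_pathways), function(i) {
      generate_synthetic_pathway(
        n_nodes,
        loop_fraction = if (with_loop && i == n_pathways) 0.1 else 0,
        inhibition_fraction = inhibition_fraction,
        gene_ids = genes,
        pathway_id = sprintf("SP%02d", i),
        seed = seed * 1000L + i)
    })
    spec <- cohort_spec("flat_normal", n_samples = n_samples, genes = genes)
    report <- estimate_fpr(pathways, spec, repetitions = repetitions,
                           alpha = alpha, seed = seed)
    jsonlite::write_json(
      report[c("metric", "repetitions", "estimate", "conf_int", "alpha",
               "n_circuits", "config")],
      file.path(output_dir, "fpr_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(
      data.frame(repetition = seq_along(report$per_repetition),
                 fraction_significant = report$per_repetition),
      file.path(output_dir, "fpr_per_repetition.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(output_dir, config)
    invisible(report)
  })
}

#' Sensitivity benchmark on synthetic pathways (subcommand `simulate-tpr`)
#'
#' Generates synthetic pathways, draws a flat-normal cohort, injects a
#' fold-change on the first canonical circuit's genes of each designated
#' pathway into the case samples, and runs [estimate_tpr()].
#'
#' @param output_dir Output directory.
#' @param n_pathways,n_nodes,inhibition_fraction,n_genes As in
#'   [run_simulate_fpr()].
#' @param n_case,n_control Group sizes.
#' @param fold Injected fold-change.
#' @param alpha FDR threshold.
#' @param seed Integer seed.
#' @return Invisibly, the `ccaa_benchmark` report.
#' @export
run_simulate_tpr <- function(output_dir, n_pathways = 3L, n_nodes = 15L,
                             inhibition_fraction = 0.2, n_genes = 1000L,
                             n_case = 100L, n_control = 100L, fold = 1.5,
                             alpha = 0.05, seed = 1L) {
  config <- as.list(environment())
  with_clean_outputs(output_dir, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    pathways <- lapply(seq_len(n_pathways), function(i) {
      generate_synthetic_pathway(n_nodes, loop_fraction = 0,
                                 inhibition_fraction = inhibition_fraction,
                                 gene_ids = genes,
                                 pathway_id = sprintf("SP%02d", i),
                                 seed = seed * 1000L + i)
    })
    case <- generate_cohort(cohort_spec("flat_normal", n_case, genes = genes,
                                        seed = seed + 7L))
    colnames(case) <- paste0("case_", colnames(case))
    control <- generate_cohort(cohort_spec("flat_normal", n_control,
                                           genes = genes, seed = seed + 13L))
    colnames(control) <- paste0("ctrl_", colnames(control))
    for (p in pathways) {
      circ <- decompose_circuits(p)$circuits[[1L]]
      case <- inject_signal(case,
                            unique(unlist(circ$node_genes, use.names = FALSE)),
                            fold = fold)
    }
    report <- estimate_tpr(pathways, case, control,
                           cancer_pathway_ids = vapply(pathways, `[[`,
                                                       character(1),
                                                       "pathway_id"),
                           alpha = alpha)
    jsonlite::write_json(
      report[c("metric", "estimate", "conf_int", "alpha", "config")],
      file.path(output_dir, "tpr_report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write.table(report$detected, file.path(output_dir, "tpr_detected.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(output_dir, config)
    invisible(report)
  })
}

#' Decompose pathways to a circuit table (subcommand `decompose`)
#'
#' @param pathway_files Pathway file paths.
#' @param output_dir Output directory.
#' @param dialect Pathway dialect.
#' @return Invisibly, the metadata `data.frame` written to
#'   `circuits.tsv`.
#' @export
run_decompose <- function(pathway_files, output_dir,
                          dialect = "native_json") {
  config <- run_config(pathway_files = pathway_files, dialect = dialect)
  with_clean_outputs(output_dir, {
    pathways <- load_pathway_files(pathway_files, dialect)
    meta <- do.call(rbind, lapply(pathways, function(p) {
      dec <- decompose_circuits(p)
      do.call(rbind, c(lapply(c(dec$circuits, dec$effector_circuits),
                              circuit_metadata_row),
                       make.row.names = FALSE))
    }))
    rownames(meta) <- NULL
    out <- file.path(output_dir, "circuits.tsv")
    con <- file(out, "w")
    writeLines(paste0("# config_hash: ", config_hash(config)), con)
    write.table(meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
    write_provenance(output_dir, config)
    invisible(meta)
  })
}
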