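# Plain-text readers and writers for every on-disk format the pipeline
# speaks (TSV matrices and designs, long-format Ct tables, study-summary
# CSV, GMT gene sets), plus the pipeline driver with JSON provenance.
# Native dialect: tab-separated values with '#'-prefixed header comments.

mt_version <- function() as.character(utils::packageVersion("mirtrend"))

write_mt_table <- function(df, path, params = NULL, sep = "\t") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# mirtrend ", mt_version(),
                    if (!is.null(params)) paste0("; ", params) else ""), con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_mt_table <- function(path, sep = "\t") {
  if (!file.exists(path)) mt_parse_error(path, "file does not exist")
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

check_numeric_cells <- function(df, path, id_col = 1L) {
  raw <- df[, -id_col, drop = FALSE]
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !is.na(raw[[j]]))
    if (length(bad))
      mt_parse_error(path, "non-numeric cell at data row %d, column '%s'",
                     bad[1], names(raw)[j])
    raw[[j]] <- v
  }
  m <- as.matrix(raw)
  rownames(m) <- df[[id_col]]
  m
}

#' Read a count matrix and its design into a pool count table
#'
#' The counts file is a TSV whose first column holds feature ids and whose
#' header holds sample ids; the design file is a TSV with columns
#' `sample_id` and `group`. Lines starting with `#` are comments.
#'
#' @param path counts TSV.
#' @param design_path design TSV.
#' @return a [pool_count_table()].
#' @export
read_count_table <- function(path, design_path) {
  df <- read_mt_table(path)
  if (ncol(df) < 2L) mt_parse_error(path, "need an id column plus samples")
  if (anyDuplicated(df[[1L]])) {
    d <- df[[1L]][duplicated(df[[1L]])][1]
    mt_parse_error(path, "duplicate feature id '%s' (data row %d)", d,
                   which(df[[1L]] == d)[2])
  }
  counts <- check_numeric_cells(df, path)
  design <- read_design(design_path)
  miss <- setdiff(colnames(counts), design$sample_id)
  if (length(miss))
    mt_parse_error(design_path, "sample '%s' missing from the design", miss[1])
  pool_count_table(counts,
                   stats::setNames(design$group, design$sample_id))
}

#' Read a sample-to-group design file
#'
#' @param path TSV with columns `sample_id`, `group`.
#' @return data.frame with those two columns.
#' @export
read_design <- function(path) {
  df <- read_mt_table(path)
  if (!all(c("sample_id", "group") %in% names(df)))
    mt_parse_error(path, "needs columns sample_id, group")
  if (anyDuplicated(df$sample_id))
    mt_parse_error(path, "duplicate sample_id '%s'",
                   df$sample_id[duplicated(df$sample_id)][1])
  df
}

#' Read a long-format Ct table
#'
#' @param path TSV with columns `sample`, `condition`, `assay`,
#'   `replicate`, `ct`.
#' @return a [ct_table()].
#' @export
read_ct_table <- function(path) {
  df <- read_mt_table(path)
  if (!is.numeric(df$ct)) {
    v <- suppressWarnings(as.numeric(df$ct))
    if (anyNA(v)) mt_parse_error(path, "non-numeric ct at data row %d",
                                 which(is.na(v))[1])
    df$ct <- v
  }
  tryCatch(ct_table(df), mirtrend_error = function(e)
    mt_parse_error(path, conditionMessage(e)))
}

#' Read an expression matrix and two-factor design into an expression study
#'
#' @param path expression TSV (first column gene id, header sample ids).
#' @param design_path design TSV with columns `sample`, `context`,
#'   `treatment`, `replicate`.
#' @param contexts,treatments optional declared orders, see
#'   [expression_study()].
#' @return an [expression_study()].
#' @export
read_expression <- function(path, design_path, contexts = NULL,
                            treatments = NULL) {
  df <- read_mt_table(path)
  if (anyDuplicated(df[[1L]]))
    mt_parse_error(path, "duplicate gene id '%s'",
                   df[[1L]][duplicated(df[[1L]])][1])
  expr <- check_numeric_cells(df, path)
  design <- read_mt_table(design_path)
  tryCatch(expression_study(expr, design, contexts, treatments),
           mirtrend_error = function(e)
             mt_parse_error(design_path, conditionMessage(e)))
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path GMT file.
#' @return a `gene_set_collection`: list with `sets` (named list of id
#'   vectors), `descriptions`, `source`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) mt_parse_error(path, "file does not exist")
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) mt_parse_error(path, "no gene sets")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    mt_parse_error(path, "line %d has fewer than 3 fields (name, description, members)",
                   short[1])
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    mt_parse_error(path, "duplicate set name '%s'",
                   names_[duplicated(names_)][1])
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  structure(list(sets = sets,
                 descriptions = stats::setNames(vapply(fields, `[[`, "", 2L),
                                                names_),
                 source = path),
            class = "gene_set_collection")
}

#' Write gene sets in GMT format
#'
#' @param sets named list of gene-id vectors, or a `gene_set_collection`.
#' @param path output file.
#' @param descriptions optional named descriptions (default `"na"`).
#' @return the path, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (inherits(sets, "gene_set_collection")) {
    descriptions <- sets$descriptions
    sets <- sets$sets
  }
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read per-study meta-analysis summaries from CSV
#'
#' @param path CSV with columns `study`, `n_case`, `mean_case`, `sd_case`,
#'   `n_control`, `mean_control`, `sd_control`.
#' @return a [as_study_summaries()] data.frame.
#' @export
read_study_summaries <- function(path) {
  df <- read_mt_table(path, sep = ",")
  tryCatch(as_study_summaries(df), mirtrend_error = function(e)
    mt_parse_error(path, conditionMessage(e)))
}

#' Write a pool count table (counts + design) to TSV
#'
#' @param table a [pool_count_table()].
#' @param counts_path,design_path output files.
#' @return invisibly, the two paths.
#' @export
write_count_table <- function(table, counts_path, design_path) {
  df <- data.frame(mirna_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  write_mt_table(df, counts_path)
  write_mt_table(data.frame(sample_id = names(table$groups),
                            group = unname(table$groups)), design_path)
  invisible(c(counts_path, design_path))
}

#' Write an expression study (matrix + design) to TSV
#'
#' @param study an [expression_study()].
#' @param expr_path,design_path output files.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(study, expr_path, design_path) {
  df <- data.frame(gene_id = rownames(study$expr), study$expr,
                   check.names = FALSE)
  write_mt_table(df, expr_path)
  write_mt_table(study$design, design_path)
  invisible(c(expr_path, design_path))
}

#' Write a Ct table to TSV
#'
#' @param table a [ct_table()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ct_table <- function(table, path) {
  write_mt_table(as.data.frame(table), path)
}

#' Write study summaries to CSV
#'
#' @param studies a [as_study_summaries()] data.frame.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_study_summaries <- function(studies, path) {
  write_mt_table(as.data.frame(studies), path, sep = ",")
}

# --- pipeline driver --------------------------------------------------------

#' Run the full pipeline from a configuration
#'
#' The configuration is a named list (or a path to a JSON file holding one)
#' with a global `seed`, an `out_dir`, and one block per requested stage:
#' `poolcmp` (counts, design, group_a, group_b, optional use_normalized),
#' `ddct` (ct, target, references, calibrator), `meta` (summaries),
#' `screen` (expression, design, alpha, n_perm, correction, arms, optional
#' gene_list), `enrich` (gmt, n_perm, weight_exponent; requires `screen`).
#' Each stage writes a TSV under `out_dir` and the driver writes
#' `provenance.json` (tool version, seed, full configuration), from which
#' the identical run can be reproduced: a provenance file is itself a valid
#' configuration.
#'
#' @param config named list or path to a JSON configuration.
#' @return named list of stage results (invisibly also written to
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) mt_parse_error(config, "file does not exist")
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.null(config$config)) config <- config$config  # provenance re-run
  if (is.null(config$out_dir))
    mt_config_error("out_dir", "is required")
  seed <- if (is.null(config$seed)) 1L else config$seed
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      mt_stop("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  need_file <- function(block, field, name) {
    p <- block[[field]]
    if (is.null(p) || !file.exists(p))
      mt_stop("pipeline stage '%s': missing input file '%s'", name,
              if (is.null(p)) paste0("<", field, ">") else p)
    p
  }
  results <- list()
  if (!is.null(config$poolcmp)) {
    b <- config$poolcmp
    results$poolcmp <- stage("poolcmp", {
      tab <- read_count_table(need_file(b, "counts", "poolcmp"),
                              need_file(b, "design", "poolcmp"))
      un <- if (is.null(b$use_normalized)) TRUE else isTRUE(b$use_normalized)
      cmp <- compare_groups(tab, b$group_a, b$group_b, use_normalized = un)
      write_mt_table(cmp, file.path(config$out_dir, "poolcmp.tsv"),
                     params = sprintf("poolcmp %s vs %s; normalized=%s",
                                      b$group_b, b$group_a, un))
      cmp
    })
  }
  if (!is.null(config$ddct)) {
    b <- config$ddct
    results$ddct <- stage("ddct", {
      tab <- read_ct_table(need_file(b, "ct", "ddct"))
      rel <- delta_delta_ct(tab, b$target, unlist(b$references), b$calibrator)
      write_mt_table(rel, file.path(config$out_dir, "ddct.tsv"),
                     params = sprintf("ddct target=%s calibrator=%s",
                                      b$target, b$calibrator))
      rel
    })
  }
  if (!is.null(config$meta)) {
    b <- config$meta
    results$meta <- stage("meta", {
      studies <- read_study_summaries(need_file(b, "summaries", "meta"))
      res <- dersimonian_laird(studies)
      write_mt_table(forest_table(res),
                     file.path(config$out_dir, "meta_forest.tsv"),
                     params = "DerSimonian-Laird random effects, Hedges g")
      res
    })
  }
  if (!is.null(config$screen)) {
    b <- config$screen
    results$screen <- stage("screen", {
      study <- read_expression(need_file(b, "expression", "screen"),
                               need_file(b, "design", "screen"))
      gl <- NULL
      if (!is.null(b$gene_list)) {
        glp <- need_file(b, "gene_list", "screen")
        gl <- if (grepl("\\.gmt$", glp)) unique(unlist(read_gmt(glp)$sets))
              else readLines(glp)
      }
      res <- trend_screen(
        study, gene_list = gl,
        alpha = if (is.null(b$alpha)) 0.05 else b$alpha,
        n_perm = if (is.null(b$n_perm)) 10000 else b$n_perm,
        seed = seed,
        correction = if (is.null(b$correction)) "bh" else b$correction,
        arms = if (is.null(b$arms)) "three" else b$arms)
      s <- attr(res, "summary")
      write_mt_table(as.data.frame(res),
                     file.path(config$out_dir, "screen.tsv"),
                     params = sprintf("screen alpha=%s n_perm=%d seed=%s",
                                      s$alpha, s$n_perm, format(s$seed)))
      jsonlite::write_json(s, file.path(config$out_dir, "screen_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      res
    })
  }
  if (!is.null(config$enrich)) {
    b <- config$enrich
    results$enrich <- stage("enrich", {
      if (is.null(results$screen))
        mt_stop("the 'enrich' stage needs a 'screen' stage")
      sets <- read_gmt(need_file(b, "gmt", "enrich"))
      enr <- enrich_screen(
        results$screen, sets,
        n_perm = if (is.null(b$n_perm)) 10000 else b$n_perm,
        seed = seed,
        weight_exponent = if (is.null(b$weight_exponent)) 1
                          else b$weight_exponent)
      write_mt_table(enr, file.path(config$out_dir, "enrichment.tsv"),
                     params = "weighted-KS enrichment, gene-label null")
      enr
    })
  }
  provenance <- list(tool = "mirtrend", version = mt_version(), seed = seed,
                     config = config)
  jsonlite::write_json(provenance,
                       file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
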