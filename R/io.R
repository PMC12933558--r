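# Readers and writers. All tables are UTF-8 TSV with a header row; matrices
# carry the row key in the first column. Every writer has a matching reader
# and the pair is a fixpoint (write -> read -> write reproduces the file).

#' Write / read a generic TSV table
#'
#' @param df Data frame (list columns are not supported).
#' @param path File path.
#' @return `write_table_tsv` returns `path` invisibly; `read_table_tsv`
#'   returns the data frame.
#' @export
write_table_tsv <- function(df, path) {
  stopifnot(!any(vapply(df, is.list, TRUE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "NA", quote = "", encoding = "UTF-8")
}

#' Write / read a numeric matrix as TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path File path.
#' @param key_col Name of the first (row key) column.
#' @return `write_matrix_tsv` returns `path` invisibly; `read_matrix_tsv`
#'   returns the matrix.
#' @export
write_matrix_tsv <- function(mat, path, key_col = "row_key") {
  df <- data.frame(k = rownames(mat), as.data.frame(mat, optional = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- key_col
  write_table_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_table_tsv(path)
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Write / read a cluster design table
#'
#' Two columns: `sample`, `label` (A/B/unused).
#'
#' @param design A [cluster_design()].
#' @param path File path.
#' @export
write_design_tsv <- function(design, path) {
  write_table_tsv(data.frame(sample = design$sample_ids,
                             label = unname(design$labels[design$sample_ids]),
                             stringsAsFactors = FALSE), path)
}

#' @rdname write_design_tsv
#' @export
read_design_tsv <- function(path) {
  df <- read_table_tsv(path)
  cluster_design(df$sample, df$label)
}

#' Write a reference bundle as its four TSV tables
#'
#' @param bundle A [reference_bundle()].
#' @param dir Output directory (created if needed). Files: `lr_pairs.tsv`,
#'   `pathways.tsv` (long format, one member per row), `network.tsv`,
#'   `ptm_reference.tsv`.
#' @return Invisibly, the named vector of paths (usable directly as the
#'   `paths` argument of [load_reference_bundle()]).
#' @export
write_reference_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(lr_pairs = file.path(dir, "lr_pairs.tsv"),
             pathways = file.path(dir, "pathways.tsv"),
             network = file.path(dir, "network.tsv"),
             ptm_reference = file.path(dir, "ptm_reference.tsv"))
  write_table_tsv(bundle$lr_pairs, paths[["lr_pairs"]])
  pw <- do.call(rbind, lapply(bundle$pathways, function(p) {
    data.frame(pathway_id = p$pathway_id, name = p$name, source = p$source,
               member = p$members, stringsAsFactors = FALSE)
  }))
  write_table_tsv(pw, paths[["pathways"]])
  net <- bundle$network$edges
  net$directed <- as.integer(net$directed)
  write_table_tsv(net, paths[["network"]])
  write_table_tsv(bundle$ptm_records, paths[["ptm_reference"]])
  invisible(paths)
}

results_tsv_columns <- c("ligand", "receptor", "pathway_id", "pathway_name",
                         "n_targets", "p_ligand", "p_receptor", "p_pathway",
                         "p_overall", "p_overall_cal", "q_value",
                         "n_ptm_events", "n_concordant", "n_discordant",
                         "p_ptm_pathway", "q_ptm", "selected",
                         "selection_reason")

#' Write a pipeline run to a directory
#'
#' Writes `results.tsv` (the standard output schema plus the ligand/receptor
#' deltas), `events.tsv`, and `meta.json` (seed, Monte-Carlo size, config
#' echo and stage counts).
#'
#' @param run An `lri_run`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_lri_run <- function(run, dir) {
  stopifnot(inherits(run, "lri_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- run$results
  res$targets <- NULL
  cols <- c(results_tsv_columns, "ligand_delta", "receptor_delta")
  write_table_tsv(res[intersect(cols, names(res))],
                  file.path(dir, "results.tsv"))
  write_table_tsv(run$events, file.path(dir, "events.tsv"))
  jsonlite::write_json(run$meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a pipeline run written by [write_lri_run()]
#'
#' @param dir Run directory.
#' @return An `lri_run` (without the in-memory `targets` list column).
#' @export
read_lri_run <- function(dir) {
  res <- read_table_tsv(file.path(dir, "results.tsv"))
  res$selected <- as.logical(res$selected)
  ev <- read_table_tsv(file.path(dir, "events.tsv"))
  if (nrow(ev)) {
    ev$enzyme[is.na(ev$enzyme)] <- ""
    ev$enzyme_detected <- as.logical(ev$enzyme_detected)
    ev$substrate_detected <- as.logical(ev$substrate_detected)
  }
  meta_path <- file.path(dir, "meta.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  structure(list(results = res, events = ev, meta = meta), class = "lri_run")
}

#' Export a run as a Cytoscape-ready network
#'
#' Writes `<prefix>.sif` (ligand -> receptor edges typed `LR`, receptor ->
#' target edges typed `RT`, deduplicated), `<prefix>.nodes.tsv` (role and
#' delta per node; a node with several roles gets them joined by `;`) and
#' `<prefix>.edges.tsv` (p-values and concordance counts per edge). By
#' default only selected triples are exported.
#'
#' @param run An `lri_run` (must carry the in-memory `targets` column; runs
#'   re-read from disk export LR edges only).
#' @param out_prefix Path prefix for the three files.
#' @param selected_only Restrict to selected triples (default `TRUE`).
#' @return Invisibly, the vector of files written.
#' @export
export_cytoscape <- function(run, out_prefix, selected_only = TRUE) {
  stopifnot(inherits(run, "lri_run"))
  res <- run$results
  if (selected_only) res <- res[res$selected, , drop = FALSE]
  if (!nrow(res)) warning("no triples to export; writing empty files",
                          call. = FALSE)
  edges <- list()
  for (i in seq_len(nrow(res))) {
    edges[[length(edges) + 1L]] <- data.frame(
      source = res$ligand[i], type = "LR", target = res$receptor[i],
      p_overall = res$p_overall[i], p_pathway = res$p_pathway[i],
      n_concordant = res$n_concordant[i] %||% NA_integer_,
      n_discordant = res$n_discordant[i] %||% NA_integer_,
      stringsAsFactors = FALSE)
    tg <- if (!is.null(res$targets)) res$targets[[i]] else character(0)
    if (length(tg)) {
      edges[[length(edges) + 1L]] <- data.frame(
        source = res$receptor[i], type = "RT", target = tg,
        p_overall = NA_real_, p_pathway = res$p_pathway[i],
        n_concordant = res$n_concordant[i], n_discordant = res$n_discordant[i],
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    empty_df(source = character(), type = character(), target = character(),
             p_overall = numeric(), p_pathway = numeric(),
             n_concordant = integer(), n_discordant = integer())
  edges <- edges[!duplicated(edges[c("source", "type", "target")]), ,
                 drop = FALSE]

  files <- paste0(out_prefix, c(".sif", ".nodes.tsv", ".edges.tsv"))
  writeLines(if (nrow(edges)) {
    paste(edges$source, edges$type, edges$target, sep = "\t")
  } else character(0), files[1L])

  nodes <- unique(c(edges$source, edges$target))
  role <- vapply(nodes, function(nd) {
    r <- character(0)
    if (nd %in% res$ligand) r <- c(r, "ligand")
    if (nd %in% res$receptor) r <- c(r, "receptor")
    if (nd %in% unlist(edges$target[edges$type == "RT"])) r <- c(r, "target")
    paste(r, collapse = ";")
  }, "")
  delta <- vapply(nodes, function(nd) {
    if (nd %in% res$ligand) return(res$ligand_delta[match(nd, res$ligand)])
    if (nd %in% res$receptor) return(res$receptor_delta[match(nd, res$receptor)])
    NA_real_
  }, 1)
  write_table_tsv(data.frame(node = nodes, role = role, delta = delta,
                             stringsAsFactors = FALSE), files[2L])
  write_table_tsv(edges, files[3L])
  invisible(files)
}

#' Per-pathway expression-vs-PTM significance comparison table
#'
#' Merges all triples of a pathway into one row (plot-ready for the usual
#' scatter of expression versus PTM significance): mean -log10 of the
#' expression pathway p-values, mean -log10 of the PTM pathway p-values
#' (missing when no triple of the pathway has PTM events), the event count,
#' and the majority concordance call (`concordant`, `discordant`, or `mixed`
#' on ties / no calls).
#'
#' @param run An `lri_run`.
#' @return Data frame with one row per pathway.
#' @export
export_significance_comparison <- function(run) {
  stopifnot(inherits(run, "lri_run"))
  res <- run$results
  ev <- run$events
  out <- lapply(split(seq_len(nrow(res)), res$pathway_id), function(idx) {
    d <- res[idx, , drop = FALSE]
    pe <- ev[ev$pathway_id == d$pathway_id[1L], , drop = FALSE]
    pp <- d$p_ptm_pathway[!is.na(d$p_ptm_pathway)]
    n_con <- sum(pe$concordance == "concordant")
    n_dis <- sum(pe$concordance == "discordant")
    data.frame(
      pathway_id = d$pathway_id[1L],
      pathway_name = d$pathway_name[1L],
      n_triples = nrow(d),
      mean_neglog10_p_expr = mean(-log10(pmax(d$p_pathway, 1e-300))),
      mean_neglog10_p_ptm = if (length(pp)) {
        mean(-log10(pmax(pp, 1e-300)))
      } else NA_real_,
      n_ptm_events = nrow(pe),
      concordance = if (n_con > n_dis) "concordant"
        else if (n_dis > n_con) "discordant" else "mixed",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
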