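# Dedicated PTM analysis tools: crosstalk between two modification types and
# PhosphoSitePlus flat-file annotation of observed events.

run_events <- function(run, selected_only = TRUE) {
  stopifnot(inherits(run, "lri_run"))
  ev <- run$events
  if (selected_only && nrow(ev)) {
    key <- paste(run$results$ligand, run$results$receptor,
                 run$results$pathway_id, sep = "|")
    sel <- key[run$results$selected]
    ev <- ev[paste(ev$ligand, ev$receptor, ev$pathway_id, sep = "|") %in% sel,
             , drop = FALSE]
  }
  ev
}

#' Crosstalk between two PTM types
#'
#' Integrates two completed runs performed with different modification-type
#' references (e.g. phosphorylation and ubiquitination) and reports (i)
#' pathways with events of both types, (ii) ligand-receptor pairs with events
#' of both types, and (iii) substrate proteins modified by both types. All
#' lists are deduplicated and sorted, so the report is symmetric in its two
#' arguments.
#'
#' @param results_a,results_b Two [run_differential_pipeline()] outputs.
#' @param selected_only Restrict to events of selected LRIs (default `TRUE`).
#' @return A list of class `crosstalk_report` with `shared_pathways`
#'   (character), `shared_lris` (data frame `ligand`, `receptor`) and
#'   `dual_modified_proteins` (character).
#' @export
crosstalk <- function(results_a, results_b, selected_only = TRUE) {
  ea <- run_events(results_a, selected_only)
  eb <- run_events(results_b, selected_only)
  ta <- sort(unique(ea$ptm_type))
  tb <- sort(unique(eb$ptm_type))
  if (length(ta) && identical(ta, tb)) {
    warning("both runs carry the same PTM type(s): ",
            paste(ta, collapse = ", "), call. = FALSE)
  }
  lri_a <- unique(ea[c("ligand", "receptor")])
  lri_b <- unique(eb[c("ligand", "receptor")])
  shared_lris <- merge(lri_a, lri_b, by = c("ligand", "receptor"))
  shared_lris <- shared_lris[order(shared_lris$ligand, shared_lris$receptor),
                             , drop = FALSE]
  rownames(shared_lris) <- NULL
  structure(list(
    shared_pathways = sort(intersect(unique(ea$pathway_id),
                                     unique(eb$pathway_id))),
    shared_lris = shared_lris,
    dual_modified_proteins = sort(intersect(unique(ea$protein),
                                            unique(eb$protein)))
  ), class = "crosstalk_report")
}

#' @export
print.crosstalk_report <- function(x, ...) {
  cat("crosstalk_report:", length(x$shared_pathways), "shared pathways,",
      nrow(x$shared_lris), "shared LRIs,",
      length(x$dual_modified_proteins), "dual-modified proteins\n")
  invisible(x)
}

# PhosphoSitePlus MOD_RSD tokens look like "Y187-p": residue+position plus a
# modification suffix. Map the suffix to a modification-type name.
psp_mod_suffix_map <- c(p = "phosphorylation", ub = "ubiquitination",
                        ga = "glycosylation", gl = "glycosylation",
                        ac = "acetylation", me = "methylation",
                        m1 = "methylation", m2 = "methylation",
                        m3 = "methylation", sm = "sumoylation")

parse_mod_rsd <- function(mod_rsd) {
  m <- regmatches(mod_rsd, regexec("^([A-Za-z])([0-9]+)(-([A-Za-z0-9]+))?$",
                                   mod_rsd))
  get <- function(i) vapply(m, function(x) if (length(x) >= i) x[[i]] else "",
                            "")
  residue <- toupper(get(2L))
  position <- suppressWarnings(as.integer(get(3L)))
  suffix <- get(5L)
  ptm_type <- ifelse(suffix == "", NA_character_,
                     unname(psp_mod_suffix_map[tolower(suffix)]))
  ptm_type[is.na(ptm_type) & suffix != ""] <- tolower(suffix[is.na(ptm_type) & suffix != ""])
  data.frame(residue = residue, position = position,
             site = paste0(residue, position), ptm_type = ptm_type,
             stringsAsFactors = FALSE)
}

#' Parse a PhosphoSitePlus flat file
#'
#' Handles the PhosphoSitePlus dialect: gzip or plain tab-delimited text with
#' a short free-text preamble (normally 3 lines) before the header row. Only
#' human records are kept. Files are user-supplied (the database is
#' license-restricted); the package ships only a synthetic fixture in the
#' same dialect.
#'
#' @param path Path to `Regulatory_sites(.gz)`, `Kinase_Substrate_Dataset(.gz)`
#'   or `Disease-associated_sites(.gz)`.
#' @param kind One of `"regulatory"`, `"kinase_substrate"`, `"disease"`.
#' @return Data frame of records with normalized key columns `gene`, `site`
#'   (residue+position, e.g. `"Y187"`), `ptm_type`, plus the file's own
#'   columns.
#' @export
parse_psp_file <- function(path,
                           kind = c("regulatory", "kinase_substrate",
                                    "disease")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, open = "rt")  # reads plain text transparently too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  marker <- switch(kind,
                   regulatory = "MOD_RSD",
                   kinase_substrate = "SUB_MOD_RSD",
                   disease = "MOD_RSD")
  hdr <- which(grepl(marker, lines[seq_len(min(10L, length(lines)))],
                     fixed = TRUE))[1L]
  if (is.na(hdr)) {
    stop("header row not found within the first 10 lines; expected a ",
         "PhosphoSitePlus-dialect file with a '", marker, "' column",
         call. = FALSE)
  }
  df <- utils::read.delim(text = paste(lines[hdr:length(lines)],
                                       collapse = "\n"),
                          stringsAsFactors = FALSE, check.names = TRUE,
                          quote = "")
  if (kind == "kinase_substrate") {
    df <- df[tolower(df$KIN_ORGANISM) == "human" &
               tolower(df$SUB_ORGANISM) == "human", , drop = FALSE]
    mod <- parse_mod_rsd(df$SUB_MOD_RSD)
    df$gene <- toupper(df$SUB_GENE)
  } else {
    df <- df[tolower(df$ORGANISM) == "human", , drop = FALSE]
    mod <- parse_mod_rsd(df$MOD_RSD)
    df$gene <- toupper(df$GENE)
  }
  df$site <- mod$site
  df$ptm_type <- mod$ptm_type
  rownames(df) <- NULL
  df
}

first_or_empty <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (!length(x)) "" else paste(unique(x), collapse = "; ")
}

#' Annotate PTM events with PhosphoSitePlus information
#'
#' Left-joins events on (protein symbol, residue+position): every event is
#' preserved in order, unmatched events get empty annotation fields. The
#' kinase comes from the kinase-substrate file, functions/processes/notes
#' from the regulatory-sites file, diseases and the direction of alteration
#' from the disease-associated-sites file; the site group identifier is taken
#' from whichever file matches first.
#'
#' @param events Events data frame (from an `lri_run` or
#'   [attach_ptm_events()]).
#' @param psp Named list with any of `regulatory`, `kinase_substrate`,
#'   `disease` as returned by [parse_psp_file()].
#' @return `events` with appended columns `psp_site_group_id`, `psp_kinase`,
#'   `psp_domain`, `psp_functions`, `psp_processes`, `psp_diseases`,
#'   `psp_alteration`, `psp_notes`, and logical `psp_matched`.
#' @export
annotate_events_psp <- function(events, psp) {
  key <- paste(toupper(events$protein),
               paste0(events$residue, events$position), sep = "|")
  reg <- psp$regulatory
  ks <- psp$kinase_substrate
  dis <- psp$disease
  pull <- function(df, k, col) {
    if (is.null(df) || is.null(df[[col]])) return("")
    first_or_empty(df[[col]][paste(df$gene, df$site, sep = "|") == k])
  }
  ann <- lapply(key, function(k) {
    sg <- c(pull(reg, k, "SITE_GRP_ID"), pull(ks, k, "SITE_GRP_ID"),
            pull(dis, k, "SITE_GRP_ID"))
    sg <- sg[nzchar(sg)]
    list(psp_site_group_id = if (length(sg)) sg[[1L]] else "",
         psp_kinase = pull(ks, k, "GENE"),
         psp_domain = first_or_empty(c(pull(reg, k, "DOMAIN"),
                                       pull(ks, k, "DOMAIN"))),
         psp_functions = pull(reg, k, "ON_FUNCTION"),
         psp_processes = pull(reg, k, "ON_PROCESS"),
         psp_diseases = pull(dis, k, "DISEASE"),
         psp_alteration = pull(dis, k, "ALTERATION"),
         psp_notes = first_or_empty(c(pull(reg, k, "NOTES"),
                                      pull(dis, k, "NOTES"))))
  })
  for (col in c("psp_site_group_id", "psp_kinase", "psp_domain",
                "psp_functions", "psp_processes", "psp_diseases",
                "psp_alteration", "psp_notes")) {
    events[[col]] <- vapply(ann, function(a) as.character(a[[col]]), "")
  }
  events$psp_matched <- apply(
    events[c("psp_site_group_id", "psp_kinase", "psp_functions",
             "psp_diseases")], 1L, function(r) any(nzchar(r)))
  events
}
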