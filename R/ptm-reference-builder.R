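# Build direction-aware PTM-pathway reference records from a neutral JSON
# export of biochemical reactions. For each reaction, modification states of a
# protein are compared between the reactant and product sides; a site present
# only on the product side is "added", one present only on the reactant side is
# "removed". Each diffed site is linked to every catalysing enzyme and every
# pathway the reaction is annotated to.
#
# The reaction export schema (reactions.json) is a list of objects:
#   {reaction_id, is_candidate, pathway_ids: [...], catalysts: [...],
#    inputs:  [{protein, complex_id, complex_size, mods: [{residue, position, ptm_type}]}],
#    outputs: [...]}
# A converter from a live graph-database dump would emit this format; the
# builder itself never talks to a database so it stays testable offline.

#' Builder configuration
#'
#' @param max_complex_size Entities that are part of a complex larger than
#'   this are ignored, to avoid excessive connectivity from very large
#'   complexes (default 10; entities *at* the threshold are retained).
#' @return A list of class `builder_config`.
#' @export
builder_config <- function(max_complex_size = 10L) {
  stopifnot(is.numeric(max_complex_size), max_complex_size >= 1)
  structure(list(max_complex_size = as.integer(max_complex_size)),
            class = "builder_config")
}

#' Read a reaction-graph JSON export
#'
#' @param path Path to a `reactions.json` file (see the package vignette for
#'   the schema).
#' @return A list of reaction records.
#' @export
read_reactions_json <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(seq_along(raw), function(i) as_reaction(raw[[i]], i))
}

as_reaction <- function(x, i) {
  if (is.null(x$reaction_id)) {
    stop(sprintf("reaction %d: missing reaction_id", i), call. = FALSE)
  }
  ent <- function(e, side) {
    if (is.null(e$protein) || !nzchar(e$protein)) {
      stop(sprintf("reaction %s: %s entity missing protein", x$reaction_id,
                   side), call. = FALSE)
    }
    mods <- lapply(e$mods %||% list(), function(m) {
      pos <- as.integer(m$position)
      if (is.na(pos) || pos < 1L) {
        stop(sprintf("reaction %s: invalid mod position for %s",
                     x$reaction_id, e$protein), call. = FALSE)
      }
      list(residue = toupper(m$residue), position = pos,
           ptm_type = as.character(m$ptm_type))
    })
    list(protein = toupper(e$protein),
         complex_id = e$complex_id,
         complex_size = if (is.null(e$complex_size)) NA_integer_ else as.integer(e$complex_size),
         mods = mods)
  }
  list(reaction_id = as.character(x$reaction_id),
       is_candidate = isTRUE(x$is_candidate),
       pathway_ids = as.character(unlist(x$pathway_ids %||% list())),
       catalysts = toupper(as.character(unlist(x$catalysts %||% list()))),
       inputs = lapply(x$inputs %||% list(), ent, side = "input"),
       outputs = lapply(x$outputs %||% list(), ent, side = "output"))
}

#' Filter reactions before diffing
#'
#' Reactions flagged as candidate (tentative) interactions are excluded to
#' minimise false positives; within retained reactions, entities belonging to
#' complexes strictly larger than `max_complex_size` are dropped.
#'
#' @param reactions List of reaction records ([read_reactions_json()]).
#' @param config A [builder_config()].
#' @return The filtered reaction list.
#' @export
filter_reactions <- function(reactions, config = builder_config()) {
  reactions <- lapply(reactions, normalize_reaction)
  reactions <- Filter(function(r) !r$is_candidate, reactions)
  lapply(reactions, function(r) {
    small <- function(e) is.na(e$complex_size) ||
      e$complex_size <= config$max_complex_size
    r$inputs <- Filter(small, r$inputs)
    r$outputs <- Filter(small, r$outputs)
    r
  })
}

# Accept both the reader's normalized shape and hand-built structures with
# list-typed fields.
normalize_reaction <- function(r) {
  r$catalysts <- toupper(as.character(unlist(r$catalysts)))
  r$pathway_ids <- as.character(unlist(r$pathway_ids))
  fix_entity <- function(e) {
    e$protein <- toupper(e$protein)
    e$complex_size <- if (is.null(e$complex_size)) NA_integer_ else
      as.integer(e$complex_size)
    e$mods <- lapply(e$mods %||% list(), function(m) {
      list(residue = toupper(m$residue), position = as.integer(m$position),
           ptm_type = as.character(m$ptm_type))
    })
    e
  }
  r$inputs <- lapply(r$inputs %||% list(), fix_entity)
  r$outputs <- lapply(r$outputs %||% list(), fix_entity)
  r
}

mods_key <- function(mods) {
  vapply(mods, function(m) paste(m$residue, m$position, m$ptm_type, sep = "|"),
         "")
}

#' Diff modification states between reactant and product entities
#'
#' @param input_entity,output_entity Reaction entities for the same protein
#'   (a mismatch is an error: it indicates a pairing bug upstream).
#' @return A data frame with columns `residue`, `position`, `ptm_type`,
#'   `direction` (`"added"` for sites only on the product side, `"removed"`
#'   for sites only on the reactant side); zero rows when the states agree.
#' @export
diff_ptm_positions <- function(input_entity, output_entity) {
  if (input_entity$protein != output_entity$protein) {
    stop("entity pairing bug: proteins differ (",
         input_entity$protein, " vs ", output_entity$protein, ")",
         call. = FALSE)
  }
  ik <- mods_key(input_entity$mods)
  ok <- mods_key(output_entity$mods)
  pick <- function(entity, keys, keep, direction) {
    sel <- !duplicated(keys) & keys %in% keep
    mods <- entity$mods[sel]
    data.frame(residue = vapply(mods, `[[`, "", "residue"),
               position = vapply(mods, `[[`, 1L, "position"),
               ptm_type = vapply(mods, `[[`, "", "ptm_type"),
               direction = rep(direction, length(mods)),
               stringsAsFactors = FALSE)
  }
  rbind(pick(output_entity, ok, setdiff(ok, ik), "added"),
        pick(input_entity, ik, setdiff(ik, ok), "removed"))
}

# Union the mods of all entities of one protein on one reaction side.
pool_side <- function(entities) {
  proteins <- vapply(entities, `[[`, "", "protein")
  lapply(split(entities, proteins), function(es) {
    mods <- do.call(c, lapply(es, `[[`, "mods"))
    mods <- mods[!duplicated(mods_key(mods))]
    list(protein = es[[1]]$protein, mods = mods,
         complex_id = NULL, complex_size = NA_integer_)
  })
}

#' Build the PTM-pathway reference from reactions
#'
#' Applies [filter_reactions()], pairs input/output entities by protein symbol
#' (multiple occurrences of a protein on one side have their modification sets
#' unioned first), diffs modification states with [diff_ptm_positions()], and
#' emits one record per (diffed site) x (catalyst) x (pathway). Reactions with
#' no catalyst emit records with an empty enzyme; reactions with no pathway
#' annotation are emitted under pathway `"UNASSIGNED"` (dropped later at
#' bundle load). A protein present on only one side is treated as fully
#' added/removed and logged.
#'
#' @param reactions List of reaction records.
#' @param config A [builder_config()].
#' @return Deduplicated data frame in the `ptm_records` schema.
#' @export
build_ptm_reference <- function(reactions, config = builder_config()) {
  reactions <- filter_reactions(reactions, config)
  out <- list()
  for (r in reactions) {
    ins <- pool_side(r$inputs)
    outs <- pool_side(r$outputs)
    proteins <- union(names(ins), names(outs))
    unpaired <- proteins[!(proteins %in% names(ins) & proteins %in% names(outs))]
    if (length(unpaired)) {
      message("reaction ", r$reaction_id, ": unpaired entit",
              if (length(unpaired) > 1) "ies " else "y ",
              paste(unpaired, collapse = ", "),
              " treated as fully added/removed")
    }
    empty_ent <- function(p) list(protein = p, mods = list())
    for (p in proteins) {
      d <- diff_ptm_positions(ins[[p]] %||% empty_ent(p),
                              outs[[p]] %||% empty_ent(p))
      if (!nrow(d)) next
      enzymes <- if (length(r$catalysts)) r$catalysts else ""
      pathways <- if (length(r$pathway_ids)) r$pathway_ids else "UNASSIGNED"
      grid <- expand.grid(i = seq_len(nrow(d)), enzyme = enzymes,
                          pathway_id = pathways, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        protein = p,
        residue = d$residue[grid$i],
        position = d$position[grid$i],
        ptm_type = d$ptm_type[grid$i],
        direction = d$direction[grid$i],
        enzyme = grid$enzyme,
        pathway_id = grid$pathway_id,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_ptm_records())
  res <- do.call(rbind, out)
  res <- res[!duplicated(res), , drop = FALSE]
  res <- res[order(res$protein, res$position, res$ptm_type, res$direction,
                   res$enzyme, res$pathway_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write PTM reference records to TSV
#'
#' @param records Data frame in the `ptm_records` schema.
#' @param path Output file path; with `split_by_type = TRUE`, one file per
#'   `ptm_type` is written, suffixing the type before the extension.
#' @param split_by_type Write one file per modification type?
#' @return Invisibly, the vector of files written.
#' @export
write_ptm_reference <- function(records, path, split_by_type = FALSE) {
  if (!split_by_type) {
    write_table_tsv(records, path)
    return(invisible(path))
  }
  types <- unique(records$ptm_type)
  if (!length(types)) {
    write_table_tsv(records, path)
    return(invisible(path))
  }
  base <- sub("\\.tsv$", "", path)
  files <- vapply(types, function(tp) {
    f <- paste0(base, ".", gsub("[^A-Za-z0-9_.-]", "_", tp), ".tsv")
    write_table_tsv(records[records$ptm_type == tp, , drop = FALSE], f)
    f
  }, "")
  invisible(unname(files))
}
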