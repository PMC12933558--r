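# Reference data model: ligand-receptor pairs, pathway definitions, the
# partially directed intracellular network, and the direction-aware PTM-pathway
# reference. Receptor targets are derived by pathway-restricted traversal.

#' Construct a pathway definition
#'
#' @param pathway_id Unique pathway identifier.
#' @param name Human-readable name.
#' @param source Provenance, one of `"reactome"`, `"gobp"`, `"user"`.
#' @param members Character vector of member protein symbols (non-empty;
#'   upper-cased on construction).
#' @return An object of class `pathway_def`.
#' @export
pathway_def <- function(pathway_id, name = pathway_id, source = "user",
                        members) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            nzchar(pathway_id))
  match_choice(source, c("reactome", "gobp", "user"), "source")
  members <- unique(toupper(as.character(members)))
  members <- members[nzchar(members)]
  if (!length(members)) stop("pathway members must be non-empty", call. = FALSE)
  structure(list(pathway_id = pathway_id, name = name, source = source,
                 members = members),
            class = "pathway_def")
}

#' Construct a partially directed intracellular network
#'
#' Self-loops are dropped; undirected edges are stored once with canonically
#' ordered endpoints; duplicate edges are removed.
#'
#' @param edges Data frame with columns `source`, `target` (protein symbols)
#'   and `directed` (logical or 0/1).
#' @return An object of class `intracellular_network` wrapping the cleaned
#'   edge table.
#' @export
intracellular_network <- function(edges) {
  if (!all(c("source", "target", "directed") %in% names(edges))) {
    stop("edges must have columns source, target, directed", call. = FALSE)
  }
  edges <- data.frame(source = toupper(as.character(edges$source)),
                      target = toupper(as.character(edges$target)),
                      directed = as.logical(as.integer(as.logical(edges$directed))),
                      stringsAsFactors = FALSE)
  loops <- edges$source == edges$target
  if (any(loops)) {
    message(sum(loops), " self-loop edge(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  flip <- !edges$directed & edges$source > edges$target
  tmp <- edges$source[flip]
  edges$source[flip] <- edges$target[flip]
  edges$target[flip] <- tmp
  dup <- duplicated(edges)
  if (any(dup)) {
    message(sum(dup), " duplicate edge(s) dropped")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  structure(list(edges = edges), class = "intracellular_network")
}

network_nodes <- function(network) {
  unique(c(network$edges$source, network$edges$target))
}

#' Assemble a validated reference bundle
#'
#' Bundles the four reference tables, enforcing referential integrity:
#' duplicate ligand-receptor pairs and PTM records are dropped (with a logged
#' count), and PTM records pointing at unknown pathways are dropped with a
#' warning.
#'
#' @param lr_pairs Data frame with columns `ligand`, `receptor`, `source`.
#' @param pathways List of [pathway_def()] objects.
#' @param network An [intracellular_network()].
#' @param ptm_records Data frame with columns `protein`, `residue`, `position`,
#'   `ptm_type`, `direction`, `enzyme`, `pathway_id` (may have zero rows).
#' @return An object of class `reference_bundle`.
#' @export
reference_bundle <- function(lr_pairs, pathways, network,
                             ptm_records = empty_ptm_records()) {
  stopifnot(all(c("ligand", "receptor") %in% names(lr_pairs)))
  if (is.null(lr_pairs$source)) lr_pairs$source <- ""
  lr_pairs <- data.frame(ligand = toupper(as.character(lr_pairs$ligand)),
                         receptor = toupper(as.character(lr_pairs$receptor)),
                         source = as.character(lr_pairs$source),
                         stringsAsFactors = FALSE)
  if (any(!nzchar(lr_pairs$ligand)) || any(!nzchar(lr_pairs$receptor))) {
    stop("ligand and receptor symbols must be non-empty", call. = FALSE)
  }
  dup <- duplicated(lr_pairs[c("ligand", "receptor")])
  if (any(dup)) {
    message(sum(dup), " duplicate ligand-receptor pair(s) dropped")
    lr_pairs <- lr_pairs[!dup, , drop = FALSE]
  }
  rownames(lr_pairs) <- NULL

  if (inherits(pathways, "pathway_def")) pathways <- list(pathways)
  stopifnot(all(vapply(pathways, inherits, TRUE, "pathway_def")))
  ids <- vapply(pathways, `[[`, "", "pathway_id")
  if (anyDuplicated(ids)) stop("pathway_id values must be unique", call. = FALSE)
  names(pathways) <- ids

  stopifnot(inherits(network, "intracellular_network"))

  ptm_records <- validate_ptm_records(ptm_records, known_pathways = ids)

  structure(list(lr_pairs = lr_pairs, pathways = pathways, network = network,
                 ptm_records = ptm_records),
            class = "reference_bundle")
}

empty_ptm_records <- function() {
  empty_df(protein = character(), residue = character(), position = integer(),
           ptm_type = character(), direction = character(), enzyme = character(),
           pathway_id = character())
}

validate_ptm_records <- function(ptm_records, known_pathways = NULL) {
  need <- c("protein", "residue", "position", "ptm_type", "direction",
            "enzyme", "pathway_id")
  if (!all(need %in% names(ptm_records))) {
    stop("ptm_records must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ptm_records <- ptm_records[need]
  ptm_records$protein <- toupper(as.character(ptm_records$protein))
  ptm_records$residue <- toupper(as.character(ptm_records$residue))
  ptm_records$position <- as.integer(ptm_records$position)
  ptm_records$ptm_type <- as.character(ptm_records$ptm_type)
  ptm_records$direction <- as.character(ptm_records$direction)
  ptm_records$enzyme <- toupper(as.character(ptm_records$enzyme))
  ptm_records$enzyme[is.na(ptm_records$enzyme)] <- ""
  ptm_records$pathway_id <- as.character(ptm_records$pathway_id)
  if (nrow(ptm_records)) {
    if (any(is.na(ptm_records$position) | ptm_records$position < 1L)) {
      stop("PTM record positions must be integers >= 1", call. = FALSE)
    }
    if (!all(ptm_records$direction %in% c("added", "removed"))) {
      stop("PTM record direction must be 'added' or 'removed'", call. = FALSE)
    }
    dup <- duplicated(ptm_records)
    if (any(dup)) {
      message(sum(dup), " duplicate PTM record(s) dropped")
      ptm_records <- ptm_records[!dup, , drop = FALSE]
    }
    if (!is.null(known_pathways)) {
      orphan <- !ptm_records$pathway_id %in% known_pathways
      if (any(orphan)) {
        warning(sum(orphan),
                " PTM record(s) referencing unknown pathways dropped",
                call. = FALSE)
        ptm_records <- ptm_records[!orphan, , drop = FALSE]
      }
    }
  }
  rownames(ptm_records) <- NULL
  ptm_records
}

#' Load a reference bundle from TSV files
#'
#' Expects four UTF-8 tab-separated files with header rows:
#' \describe{
#'   \item{lr_pairs}{columns `ligand, receptor, source`}
#'   \item{pathways}{columns `pathway_id, name, source, member` (one member per
#'     row)}
#'   \item{network}{columns `source, target, directed` with `directed` in 0/1}
#'   \item{ptm_reference}{columns `protein, residue, position, ptm_type,
#'     direction, enzyme, pathway_id`; optional}
#' }
#'
#' @param paths Named list/character vector mapping table names (`lr_pairs`,
#'   `pathways`, `network`, and optionally `ptm_reference`) to file paths.
#' @return A validated [reference_bundle()].
#' @export
load_reference_bundle <- function(paths) {
  need <- c("lr_pairs", "pathways", "network")
  missing_names <- setdiff(need, names(paths))
  if (length(missing_names)) {
    stop("paths must name: ", paste(need, collapse = ", "), call. = FALSE)
  }
  for (nm in intersect(c(need, "ptm_reference"), names(paths))) {
    if (!file.exists(paths[[nm]])) {
      stop("file not found for '", nm, "': ", paths[[nm]], call. = FALSE)
    }
  }
  read <- function(p) utils::read.delim(p, stringsAsFactors = FALSE,
                                        check.names = FALSE, na.strings = "NA")
  lr <- read(paths[["lr_pairs"]])
  pw_long <- read(paths[["pathways"]])
  if (!all(c("pathway_id", "member") %in% names(pw_long))) {
    stop("pathways table must have columns pathway_id, name, source, member",
         call. = FALSE)
  }
  pathways <- lapply(split(pw_long, pw_long$pathway_id), function(d) {
    pathway_def(d$pathway_id[1],
                name = as.character(d$name %||% d$pathway_id)[1],
                source = as.character(d$source %||% "user")[1],
                members = d$member)
  })
  net <- intracellular_network(read(paths[["network"]]))
  ptm <- if (!is.null(paths[["ptm_reference"]])) {
    read(paths[["ptm_reference"]])
  } else {
    empty_ptm_records()
  }
  reference_bundle(lr, unname(pathways), net, ptm)
}

#' Restrict a network to a pathway
#'
#' Keeps only edges whose two endpoints are both pathway members; edge
#' direction flags are preserved. The empty subnetwork is allowed.
#'
#' @param network An [intracellular_network()].
#' @param pathway A [pathway_def()].
#' @return The edge-induced [intracellular_network()].
#' @export
pathway_subnetwork <- function(network, pathway) {
  e <- network$edges
  keep <- e$source %in% pathway$members & e$target %in% pathway$members
  out <- network
  out$edges <- e[keep, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}

#' Receptor targets within a pathway
#'
#' Targets are the proteins reachable from the receptor in the
#' pathway-restricted network, following directed edges forward only and
#' undirected edges both ways. The receptor itself is excluded. A receptor
#' that is not a pathway member has no targets.
#'
#' @param network An [intracellular_network()].
#' @param pathway A [pathway_def()].
#' @param receptor Receptor protein symbol.
#' @return Sorted character vector of target symbols (possibly empty).
#' @export
receptor_targets <- function(network, pathway, receptor) {
  receptor <- toupper(receptor)
  if (!receptor %in% pathway$members) return(character(0))
  sub <- pathway_subnetwork(network, pathway)$edges
  if (!nrow(sub)) return(character(0))
  und <- sub[!sub$directed, , drop = FALSE]
  arcs <- rbind(sub[c("source", "target")],
                data.frame(source = und$target, target = und$source,
                           stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(arcs, directed = TRUE)
  if (!receptor %in% igraph::V(g)$name) return(character(0))
  reach <- igraph::subcomponent(g, receptor, mode = "out")$name
  sort(setdiff(reach, receptor))
}

#' Filter pathways by target count and size
#'
#' Small target sets make the rank statistic unstable and very large pathways
#' dilute specificity, so pathways are kept only when they have at least
#' `min_targets` usable targets and at most `max_members` members.
#'
#' @param pathways List of [pathway_def()].
#' @param target_sets Named list mapping `pathway_id` to its target symbol
#'   vector.
#' @param min_targets Minimum number of targets (default 5).
#' @param max_members Maximum pathway size (default 400).
#' @return The retained sublist of `pathways`.
#' @export
filter_pathways <- function(pathways, target_sets, min_targets = 5L,
                            max_members = 400L) {
  stopifnot(min_targets >= 1L, max_members >= min_targets)
  keep <- vapply(pathways, function(p) {
    tg <- target_sets[[p$pathway_id]] %||% character(0)
    length(tg) >= min_targets && length(p$members) <= max_members
  }, TRUE)
  pathways[keep]
}

#' @export
print.reference_bundle <- function(x, ...) {
  cat("reference_bundle:", nrow(x$lr_pairs), "LR pairs,",
      length(x$pathways), "pathways,",
      nrow(x$network$edges), "network edges,",
      nrow(x$ptm_records), "PTM records\n")
  invisible(x)
}
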