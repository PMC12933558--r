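# Synthetic-data generator: reference bundles and two-cluster log-scale
# intensity matrices with planted ligand/receptor/target fold changes and
# planted site-level PTM deltas, concordant or discordant with the reference
# direction. Every pipeline stage is testable offline against the emitted
# ground truth.

#' Simulation configuration
#'
#' Defaults state the simulated world once: 20 + 20 samples (a typical
#' two-arm proteomic comparison), log2-scale intensities around 20 with unit
#' standard deviation, a 3-SD planted shift (a strong but realistic
#' fold-change for a truly regulated protein), 10 pathways of 5 targets with
#' one planted ligand-receptor-pathway triple, 3 PTM sites per pathway, all
#' planted events concordant, and 5% missing cells.
#'
#' @param n_samples_a,n_samples_b Samples per cluster (>= 3).
#' @param n_ligands,n_receptors,n_pathways,targets_per_pathway Bundle sizes.
#' @param n_planted Number of planted (signal-carrying) triples.
#' @param baseline_mean,baseline_sd Log-scale intensity baseline.
#' @param effect_size Planted B-minus-A shift, in units of `baseline_sd`.
#' @param ptm_sites_per_pathway Reference PTM sites per pathway.
#' @param frac_concordant Fraction of planted events whose observed shift
#'   agrees with the reference direction.
#' @param missing_rate Fraction of missing cells in each matrix.
#' @param seed Seed for all generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples_a = 20L, n_samples_b = 20L,
                       n_ligands = 10L, n_receptors = 10L, n_pathways = 10L,
                       targets_per_pathway = 5L, n_planted = 1L,
                       baseline_mean = 20, baseline_sd = 1,
                       effect_size = 3, ptm_sites_per_pathway = 3L,
                       frac_concordant = 1, missing_rate = 0.05,
                       seed = 1L) {
  cfg <- list(n_samples_a = as.integer(n_samples_a),
              n_samples_b = as.integer(n_samples_b),
              n_ligands = as.integer(n_ligands),
              n_receptors = as.integer(n_receptors),
              n_pathways = as.integer(n_pathways),
              targets_per_pathway = as.integer(targets_per_pathway),
              n_planted = as.integer(n_planted),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              effect_size = effect_size,
              ptm_sites_per_pathway = as.integer(ptm_sites_per_pathway),
              frac_concordant = frac_concordant,
              missing_rate = missing_rate, seed = as.integer(seed))
  stopifnot(cfg$n_samples_a >= 3L, cfg$n_samples_b >= 3L,
            cfg$n_ligands >= 1L, cfg$n_receptors >= 1L, cfg$n_pathways >= 1L,
            cfg$targets_per_pathway >= 1L,
            cfg$n_planted >= 0L, cfg$n_planted <= cfg$n_pathways,
            cfg$baseline_sd > 0,
            cfg$frac_concordant >= 0, cfg$frac_concordant <= 1,
            cfg$missing_rate >= 0, cfg$missing_rate <= 1)
  structure(cfg, class = "sim_config")
}

#' Simulate a reference bundle with ground truth
#'
#' Pathway `j` contains receptor `Rj`, a kinase `Kj` and
#' `targets_per_pathway` target proteins; the network wires `Rj -> Kj` and
#' `Kj -> target` (directed), so every target is reachable from the receptor.
#' Each pathway gets one ligand-receptor pair and `ptm_sites_per_pathway`
#' phosphorylation reference records on its targets, catalysed by `Kj`, with
#' alternating added/removed direction. The first `n_planted` pathways form
#' the truth: their triples carry planted expression signal and their sites
#' planted PTM deltas (concordant for the first `frac_concordant` share,
#' discordant for the rest). Deterministic per seed.
#'
#' @param config A [sim_config()].
#' @return List with `bundle` (a [reference_bundle()]) and `truth` (list with
#'   data frames `planted_triples` and `planted_events`).
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  nm <- function(prefix, i) sprintf("%s%02d", prefix, i)
  lig <- vapply(seq_len(config$n_ligands), function(i) nm("LIG", i), "")
  rec <- vapply(seq_len(config$n_receptors), function(i) nm("REC", i), "")
  edges <- list()
  pathways <- list()
  lr <- list()
  ptm <- list()
  events <- list()
  for (j in seq_len(config$n_pathways)) {
    r <- rec[(j - 1L) %% config$n_receptors + 1L]
    l <- lig[(j - 1L) %% config$n_ligands + 1L]
    k <- nm("KIN", j)
    tg <- vapply(seq_len(config$targets_per_pathway),
                 function(i) sprintf("TGT%02d_%02d", j, i), "")
    pid <- nm("PW", j)
    pathways[[j]] <- pathway_def(pid, name = paste("synthetic pathway", j),
                                 source = "user", members = c(r, k, tg))
    lr[[j]] <- data.frame(ligand = l, receptor = r, source = "synthetic",
                          stringsAsFactors = FALSE)
    edges[[j]] <- data.frame(source = c(r, rep(k, length(tg))),
                             target = c(k, tg),
                             directed = 1L, stringsAsFactors = FALSE)
    ns <- config$ptm_sites_per_pathway
    if (ns > 0L) {
      sub <- tg[(seq_len(ns) - 1L) %% length(tg) + 1L]
      res <- c("S", "T", "Y")[(seq_len(ns) - 1L) %% 3L + 1L]
      pos <- 100L * j + seq_len(ns)
      dirs <- c("added", "removed")[(seq_len(ns) - 1L) %% 2L + 1L]
      ptm[[j]] <- data.frame(protein = sub, residue = res, position = pos,
                             ptm_type = "phosphorylation", direction = dirs,
                             enzyme = k, pathway_id = pid,
                             stringsAsFactors = FALSE)
      if (j <= config$n_planted) {
        n_con <- round(config$frac_concordant * ns)
        events[[j]] <- data.frame(
          site_key = format_site_key(sub, res, pos, "phosphorylation"),
          direction = dirs,
          concordant = seq_len(ns) <= n_con,
          stringsAsFactors = FALSE)
      }
    }
  }
  lr <- unique(do.call(rbind, lr))
  bundle <- reference_bundle(
    lr_pairs = lr,
    pathways = pathways,
    network = intracellular_network(do.call(rbind, edges)),
    ptm_records = if (length(ptm)) do.call(rbind, ptm) else empty_ptm_records())
  planted <- seq_len(config$n_planted)
  truth <- list(
    planted_triples = data.frame(
      ligand = lig[(planted - 1L) %% config$n_ligands + 1L],
      receptor = rec[(planted - 1L) %% config$n_receptors + 1L],
      pathway_id = vapply(planted, function(j) nm("PW", j), ""),
      stringsAsFactors = FALSE)[seq_len(config$n_planted), , drop = FALSE],
    planted_events = if (length(events)) do.call(rbind, events) else
      empty_df(site_key = character(), direction = character(),
               concordant = logical()))
  list(bundle = bundle, truth = truth)
}

#' Simulate expression and PTM matrices with planted signal
#'
#' Every bundle protein gets log-scale Gaussian intensities; ligand,
#' receptor, kinase and targets of planted triples are shifted by
#' `effect_size * baseline_sd` in cluster B. PTM site rows equal the parent
#' protein's value plus an independent site term, so difference-mode
#' normalization exactly isolates the site-level effect; planted events shift
#' the site term in cluster B with a sign matching the reference direction
#' for concordant events and opposing it for discordant ones. Missing cells
#' are dropped at `missing_rate`. Deterministic per seed.
#'
#' @param bundle,truth From [simulate_bundle()].
#' @param config The same [sim_config()].
#' @return List with `expr` (matrix), `ptm` (matrix or `NULL` when the bundle
#'   has no PTM records), and `design` (a [cluster_design()]).
#' @export
simulate_matrices <- function(bundle, truth, config = sim_config()) {
  stopifnot(inherits(bundle, "reference_bundle"), inherits(config, "sim_config"))
  proteins <- sort(unique(c(bundle$lr_pairs$ligand, bundle$lr_pairs$receptor,
                            unlist(lapply(bundle$pathways, `[[`, "members")),
                            network_nodes(bundle$network))))
  n_a <- config$n_samples_a
  n_b <- config$n_samples_b
  samples <- sprintf("S%03d", seq_len(n_a + n_b))
  design <- cluster_design(samples, rep(c("A", "B"), c(n_a, n_b)))
  b_cols <- which(design$labels[samples] == "B")
  shift <- config$effect_size * config$baseline_sd

  with_seed(config$seed + 1L, {
    expr <- matrix(stats::rnorm(length(proteins) * length(samples),
                                config$baseline_mean, config$baseline_sd),
                   nrow = length(proteins),
                   dimnames = list(proteins, samples))
    for (i in seq_len(nrow(truth$planted_triples))) {
      tr <- truth$planted_triples[i, ]
      pw <- bundle$pathways[[tr$pathway_id]]
      hit <- unique(c(tr$ligand, tr$receptor,
                      receptor_targets(bundle$network, pw, tr$receptor)))
      expr[hit, b_cols] <- expr[hit, b_cols] + shift
    }

    ptm <- NULL
    if (nrow(bundle$ptm_records)) {
      rec <- bundle$ptm_records
      keys <- format_site_key(rec$protein, rec$residue, rec$position,
                              rec$ptm_type)
      keep <- !duplicated(keys)
      keys <- keys[keep]
      parents <- rec$protein[keep]
      site_term <- matrix(stats::rnorm(length(keys) * length(samples),
                                       0, config$baseline_sd),
                          nrow = length(keys),
                          dimnames = list(keys, samples))
      pe <- truth$planted_events
      for (i in seq_len(nrow(pe))) {
        idx <- match(pe$site_key[i], keys)
        if (is.na(idx)) next
        sgn <- if ((pe$direction[i] == "added") == pe$concordant[i]) 1 else -1
        site_term[idx, b_cols] <- site_term[idx, b_cols] + sgn * shift
      }
      ptm <- expr[parents, , drop = FALSE] + site_term
      rownames(ptm) <- keys
    }

    if (config$missing_rate > 0) {
      drop_cells <- function(m) {
        m[stats::runif(length(m)) < config$missing_rate] <- NA_real_
        m
      }
      expr <- drop_cells(expr)
      if (!is.null(ptm)) ptm <- drop_cells(ptm)
    }
    list(expr = expr, ptm = ptm, design = design)
  })
}

#' Score recovery of planted triples
#'
#' @param run An `lri_run` from a simulated dataset.
#' @param truth Truth table from [simulate_bundle()].
#' @return Named numeric vector: `sensitivity` (planted triples selected /
#'   planted) and `false_discovery_fraction` (selected non-planted /
#'   selected; 0 when nothing is selected).
#' @export
score_recovery <- function(run, truth) {
  stopifnot(inherits(run, "lri_run"))
  res <- run$results
  key <- function(d) paste(d$ligand, d$receptor, d$pathway_id, sep = "|")
  planted <- key(truth$planted_triples)
  selected <- key(res[res$selected, , drop = FALSE])
  sens <- if (length(planted)) mean(planted %in% selected) else NA_real_
  fdf <- if (length(selected)) mean(!selected %in% planted) else 0
  c(sensitivity = sens, false_discovery_fraction = fdf)
}
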