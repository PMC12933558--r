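# Differential-mode LRI pipeline: enumerate candidate (ligand, receptor,
# pathway) triples, score them on expression evidence with sign constraints,
# refine with site-level PTM events matched against the reference, and select
# by dual thresholding (expression and PTM significance) or by a p-value
# product.

#' Inference configuration
#'
#' @param receptor_sign `"positive"` (default) requires increased receptor
#'   abundance in cluster B; `"negative"` selects inhibitory regulation.
#'   The ligand is always required to increase in cluster B.
#' @param target_sign `"any"` (default) or `"positive"`; with `"positive"`,
#'   targets regulated in the wrong direction contribute p = 1 to the pathway
#'   rank statistic.
#' @param alpha_expr Significance threshold on the expression-based LRI
#'   statistic (default 0.05).
#' @param alpha_expr_relaxed Relaxed expression threshold used when PTM
#'   evidence is significant (default 0.25); set equal to `alpha_expr` to
#'   disable PTM rescue.
#' @param alpha_ptm Threshold on the pathway PTM statistic (default 0.05).
#' @param selection_mode `"dual_threshold"` (default) or `"product"`.
#' @param min_targets,max_members Pathway filters, see [filter_pathways()].
#' @param n_mc Monte-Carlo draws for rank-statistic calibration (>= 1000).
#' @param seed Seed driving all Monte-Carlo calibration (echoed in run
#'   metadata).
#' @param ptm_position_mode `"site"` (default) keeps each site's own
#'   statistics; `"protein"` routes the PTM table through
#'   [collapse_to_protein_mode()] first.
#' @param ptm_normalization `"ratio"` (default) or `"difference"`, see
#'   [normalize_ptm()].
#' @param use_adjusted Apply the selection thresholds to BH-adjusted values
#'   (`q_value`, `q_ptm`; default `TRUE`) rather than to the raw statistics.
#' @param exact_threshold Passed to [wilcoxon_two_sided()].
#' @return A list of class `inference_config`.
#' @export
inference_config <- function(receptor_sign = c("positive", "negative"),
                             target_sign = c("any", "positive"),
                             alpha_expr = 0.05,
                             alpha_expr_relaxed = 0.25,
                             alpha_ptm = 0.05,
                             selection_mode = c("dual_threshold", "product"),
                             min_targets = 5L,
                             max_members = 400L,
                             n_mc = 10000L,
                             seed = 1L,
                             ptm_position_mode = c("site", "protein"),
                             ptm_normalization = c("ratio", "difference"),
                             use_adjusted = TRUE,
                             exact_threshold = 25L) {
  cfg <- list(
    receptor_sign = match.arg(receptor_sign),
    target_sign = match.arg(target_sign),
    alpha_expr = alpha_expr,
    alpha_expr_relaxed = alpha_expr_relaxed,
    alpha_ptm = alpha_ptm,
    selection_mode = match.arg(selection_mode),
    min_targets = as.integer(min_targets),
    max_members = as.integer(max_members),
    n_mc = as.integer(n_mc),
    seed = as.integer(seed),
    ptm_position_mode = match.arg(ptm_position_mode),
    ptm_normalization = match.arg(ptm_normalization),
    use_adjusted = isTRUE(use_adjusted),
    exact_threshold = as.integer(exact_threshold)
  )
  for (a in c("alpha_expr", "alpha_expr_relaxed", "alpha_ptm")) {
    if (!is.numeric(cfg[[a]]) || cfg[[a]] <= 0 || cfg[[a]] > 1) {
      stop(a, " must lie in (0, 1]", call. = FALSE)
    }
  }
  if (cfg$n_mc < 1000L) stop("n_mc must be >= 1000", call. = FALSE)
  structure(cfg, class = "inference_config")
}

#' Enumerate candidate (ligand, receptor, pathway) triples
#'
#' One candidate per known ligand-receptor pair and per pathway containing
#' the receptor. Both ligand and receptor must be detected (present among the
#' expression rows); targets are the receptor's reachable proteins in the
#' pathway intersected with the detected rows, and triples whose pathways fail
#' the size filters are removed.
#'
#' @param bundle A [reference_bundle()].
#' @param expr_rows Character vector of detected protein symbols.
#' @param config An [inference_config()].
#' @return Data frame with columns `ligand`, `receptor`, `pathway_id`,
#'   `pathway_name`, `n_targets` and a list column `targets`.
#' @export
enumerate_candidate_triples <- function(bundle, expr_rows,
                                        config = inference_config()) {
  expr_rows <- toupper(expr_rows)
  lr <- bundle$lr_pairs
  lr <- lr[lr$ligand %in% expr_rows & lr$receptor %in% expr_rows, ,
           drop = FALSE]
  rows <- list()
  target_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(lr))) {
    receptor <- lr$receptor[i]
    for (pw in bundle$pathways) {
      if (!receptor %in% pw$members) next
      if (length(pw$members) > config$max_members) next
      ck <- paste(pw$pathway_id, receptor, sep = "|")
      tg <- target_cache[[ck]]
      if (is.null(tg)) {
        tg <- intersect(receptor_targets(bundle$network, pw, receptor),
                        expr_rows)
        target_cache[[ck]] <- tg
      }
      if (length(tg) < config$min_targets) next
      rows[[length(rows) + 1L]] <- list(ligand = lr$ligand[i],
                                        receptor = receptor,
                                        pathway_id = pw$pathway_id,
                                        pathway_name = pw$name,
                                        targets = tg)
    }
  }
  out <- data.frame(
    ligand = vapply(rows, `[[`, "", "ligand"),
    receptor = vapply(rows, `[[`, "", "receptor"),
    pathway_id = vapply(rows, `[[`, "", "pathway_id"),
    pathway_name = vapply(rows, `[[`, "", "pathway_name"),
    n_targets = vapply(rows, function(r) length(r$targets), 1L),
    stringsAsFactors = FALSE)
  out$targets <- lapply(rows, `[[`, "targets")
  out
}

#' Score candidate triples on expression evidence
#'
#' Ligand and receptor p-values come straight from the differential table;
#' the pathway p-value is the calibrated rank statistic over the measured
#' targets' p-values. The ligand must increase in cluster B (triples with
#' `ligand_delta <= 0` are removed); the receptor's sign is enforced per
#' configuration. No significance threshold is applied here — selection
#' happens in [select_lris()] after PTM refinement.
#'
#' @param triples Output of [enumerate_candidate_triples()].
#' @param diff Differential table for the expression matrix
#'   ([differential_table()]).
#' @param config An [inference_config()].
#' @return Data frame of scored triples with columns `ligand`, `receptor`,
#'   `pathway_id`, `pathway_name`, `n_targets`, `ligand_delta`,
#'   `receptor_delta`, `p_ligand`, `p_receptor`, `p_pathway`, `p_overall`,
#'   `q_value` and list column `targets`.
#' @export
score_triples_expression <- function(triples, diff,
                                     config = inference_config()) {
  p_of <- stats::setNames(diff$p_value, diff$row_key)
  d_of <- stats::setNames(diff$delta, diff$row_key)
  n0 <- nrow(triples)
  has <- function(sym) sym %in% diff$row_key & !is.na(p_of[sym])
  keep <- has(triples$ligand) & has(triples$receptor)
  if (any(!keep)) {
    message(sum(!keep),
            " triple(s) dropped: ligand or receptor lacks a test result")
  }
  tr <- triples[keep, , drop = FALSE]
  out <- data.frame(ligand = tr$ligand, receptor = tr$receptor,
                    pathway_id = tr$pathway_id,
                    pathway_name = tr$pathway_name,
                    n_targets = tr$n_targets,
                    ligand_delta = unname(d_of[tr$ligand]),
                    receptor_delta = unname(d_of[tr$receptor]),
                    p_ligand = unname(p_of[tr$ligand]),
                    p_receptor = unname(p_of[tr$receptor]),
                    stringsAsFactors = FALSE)
  out$targets <- tr$targets

  keep <- out$ligand_delta > 0
  keep <- keep & if (config$receptor_sign == "positive") {
    out$receptor_delta > 0
  } else {
    out$receptor_delta < 0
  }
  keep[is.na(keep)] <- FALSE
  out <- out[keep, , drop = FALSE]

  p_pathway <- rep(NA_real_, nrow(out))
  for (i in seq_len(nrow(out))) {
    tg <- out$targets[[i]]
    tp <- p_of[tg]
    if (config$target_sign == "positive") {
      wrong <- !is.na(d_of[tg]) & d_of[tg] <= 0
      tp[wrong] <- 1
    }
    tp <- tp[!is.na(tp)]
    if (!length(tp)) next
    p_pathway[i] <- rank_statistic_pvalue(tp, n_mc = config$n_mc,
                                          seed = config$seed)
  }
  out$p_pathway <- p_pathway
  unmeasured <- is.na(out$p_pathway)
  if (any(unmeasured)) {
    message(sum(unmeasured), " triple(s) dropped: no measured targets")
    out <- out[!unmeasured, , drop = FALSE]
  }
  out$p_overall <- combine_lri_pvalue(out$p_ligand, out$p_receptor,
                                      out$p_pathway)
  # p_overall is the raw product (reported as such); selection and BH use its
  # null calibration, which is uniform under the null.
  out$p_overall_cal <- calibrate_product(out$p_overall, 3L)
  out$q_value <- bh_adjust(out$p_overall_cal)
  rownames(out) <- NULL
  out
}

#' Concordance of an observed PTM change with its reference direction
#'
#' A site annotated as `added` in a pathway (e.g. phosphorylated by a kinase)
#' is concordant when its observed delta is positive; a site annotated as
#' `removed` (e.g. dephosphorylated by a phosphatase) is concordant when the
#' delta is negative. A zero or missing delta is indeterminate.
#'
#' @param direction Character vector in `c("added", "removed")`.
#' @param delta Numeric vector of observed B-minus-A changes.
#' @return Character vector in `c("concordant", "discordant",
#'   "indeterminate")`.
#' @export
concordance_flag <- function(direction, delta) {
  stopifnot(all(direction %in% c("added", "removed")))
  out <- ifelse(is.na(delta) | delta == 0, "indeterminate",
         ifelse((direction == "added") == (delta > 0),
                "concordant", "discordant"))
  as.character(out)
}

#' Attach observed PTM events to a scored triple
#'
#' For every reference record of the triple's pathway, an event is created
#' when the substrate protein is detected in the expression data, the
#' annotated enzyme is either absent from the record or also detected, and
#' the site was tested in the PTM differential table. Discordant events are
#' retained (reference errors and more complex regulation are possible); they
#' are flagged, not discarded.
#'
#' @param triple One-row data frame (or list) with at least `pathway_id`.
#' @param ptm_records Reference PTM records (bundle `ptm_records`).
#' @param ptm_diff Differential table of the normalized PTM matrix.
#' @param expr_rows Detected protein symbols.
#' @return Data frame of events: `protein`, `residue`, `position`,
#'   `ptm_type`, `direction`, `enzyme`, `site_key`, `delta`, `p_value`,
#'   `enzyme_detected`, `substrate_detected`, `concordance`.
#' @export
attach_ptm_events <- function(triple, ptm_records, ptm_diff, expr_rows) {
  expr_rows <- toupper(expr_rows)
  recs <- ptm_records[ptm_records$pathway_id == triple$pathway_id, ,
                      drop = FALSE]
  empty <- empty_df(protein = character(), residue = character(),
                    position = integer(), ptm_type = character(),
                    direction = character(), enzyme = character(),
                    site_key = character(), delta = numeric(),
                    p_value = numeric(), enzyme_detected = logical(),
                    substrate_detected = logical(), concordance = character())
  if (!nrow(recs)) return(empty)
  keep <- recs$protein %in% expr_rows &
    (recs$enzyme == "" | recs$enzyme %in% expr_rows)
  recs <- recs[keep, , drop = FALSE]
  if (!nrow(recs)) return(empty)
  recs$site_key <- format_site_key(recs$protein, recs$residue, recs$position,
                                   recs$ptm_type)
  idx <- match(recs$site_key, ptm_diff$row_key)
  recs <- recs[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  if (!nrow(recs)) return(empty)
  recs$delta <- ptm_diff$delta[idx]
  recs$p_value <- ptm_diff$p_value[idx]
  recs$enzyme_detected <- recs$enzyme != ""
  recs$substrate_detected <- TRUE
  recs$concordance <- concordance_flag(recs$direction, recs$delta)
  recs$pathway_id <- NULL
  rownames(recs) <- NULL
  recs
}

#' Pathway-level PTM regulation p-value
#'
#' The calibrated rank statistic over the event p-values, exactly as for
#' expression targets; missing when the triple has no event with a usable
#' p-value.
#'
#' @param events Data frame from [attach_ptm_events()].
#' @param n_mc,seed Calibration parameters, see [rank_statistic_pvalue()].
#' @return A p-value, or `NA` when there are no usable events.
#' @export
pathway_ptm_pvalue <- function(events, n_mc = 10000L, seed = 1L) {
  ps <- events$p_value
  ps <- ps[!is.na(ps)]
  if (!length(ps)) return(NA_real_)
  rank_statistic_pvalue(ps, n_mc = n_mc, seed = seed)
}

#' Select LRIs by dual thresholding or p-value product
#'
#' The expression selection statistic is the null-calibrated product
#' `p_overall_cal` (see [calibrate_product()]; the raw product is reported
#' but is not uniform under the null), BH-adjusted to `q_value` by default.
#' In `dual_threshold` mode an LRI is selected when its expression statistic
#' passes `alpha_expr` (reason `expression_only`, upgraded to `ptm_confirmed`
#' when the PTM statistic also passes `alpha_ptm`), or when the expression
#' statistic only passes the relaxed threshold but significant PTM evidence
#' rescues it (reason `ptm_rescued`). In `product` mode the PTM statistic is
#' multiplied in as a fourth factor (missing PTM statistic contributes a
#' neutral factor), the product is calibrated likewise, and thresholded at
#' `alpha_expr`. With `config$use_adjusted` (the default) the thresholds
#' apply to BH-adjusted values; the expression and PTM statistics are
#' corrected as two separate families.
#'
#' @param results Data frame with columns `p_overall`, `q_value`,
#'   `p_ptm_pathway`, `q_ptm`.
#' @param config An [inference_config()].
#' @return `results` with `selected` (logical) and `selection_reason`
#'   (`expression_only`, `ptm_confirmed`, `ptm_rescued`, `rejected`) set.
#' @export
select_lris <- function(results, config = inference_config()) {
  if (!nrow(results)) {
    results$selected <- logical(0)
    results$selection_reason <- character(0)
    return(results)
  }
  stopifnot(all(c("p_overall", "q_value", "p_ptm_pathway", "q_ptm") %in%
                  names(results)))
  if (is.null(results$p_overall_cal)) {
    results$p_overall_cal <- calibrate_product(results$p_overall, 3L)
  }
  expr_stat <- if (config$use_adjusted) results$q_value else
    results$p_overall_cal
  ptm_stat <- if (config$use_adjusted) results$q_ptm else results$p_ptm_pathway
  ptm_ok <- !is.na(ptm_stat) & ptm_stat <= config$alpha_ptm

  if (config$selection_mode == "product") {
    has_ptm <- !is.na(results$p_ptm_pathway)
    prod_raw <- results$p_overall * ifelse(has_ptm, results$p_ptm_pathway, 1)
    prod_stat <- calibrate_product(prod_raw, 3L)
    prod_stat[has_ptm] <- calibrate_product(prod_raw[has_ptm], 4L)
    if (config$use_adjusted) prod_stat <- bh_adjust(prod_stat)
    selected <- prod_stat <= config$alpha_expr
    reason <- ifelse(!selected, "rejected",
                     ifelse(is.na(results$p_ptm_pathway), "expression_only",
                            "ptm_confirmed"))
  } else {
    pass_expr <- expr_stat <= config$alpha_expr
    rescue <- !pass_expr & expr_stat <= config$alpha_expr_relaxed & ptm_ok
    selected <- pass_expr | rescue
    reason <- ifelse(pass_expr & ptm_ok, "ptm_confirmed",
              ifelse(pass_expr, "expression_only",
              ifelse(rescue, "ptm_rescued", "rejected")))
  }
  results$selected <- selected
  results$selection_reason <- reason
  results
}

#' Collapse site-level PTM statistics to global protein mode
#'
#' For every (protein, modification type), the most extreme regulation — the
#' site with the smallest p-value — replaces the statistics of all that
#' protein's sites (its delta and p-value are broadcast to every site key).
#' Ties on the p-value are broken by larger `|delta|`, then by
#' lexicographically smallest site key. Idempotent.
#'
#' @param ptm_diff Differential table keyed by site keys.
#' @return The collapsed differential table (same rows and order).
#' @export
collapse_to_protein_mode <- function(ptm_diff) {
  info <- parse_site_keys(ptm_diff$row_key)
  grp <- paste(info$protein, info$ptm_type, sep = "|")
  grp[!info$ok] <- NA
  out <- ptm_diff
  for (g in unique(grp[!is.na(grp)])) {
    idx <- which(grp %in% g)
    cand <- idx[!is.na(ptm_diff$p_value[idx])]
    if (!length(cand)) next
    ord <- order(ptm_diff$p_value[cand], -abs(ptm_diff$delta[cand]),
                 ptm_diff$row_key[cand])
    win <- cand[ord[1L]]
    out$delta[idx] <- ptm_diff$delta[win]
    out$p_value[idx] <- ptm_diff$p_value[win]
  }
  out$q_value <- bh_adjust(out$p_value)
  out
}

#' Run the full differential-mode pipeline
#'
#' Composes PTM normalization, per-row differential testing of both matrices,
#' candidate enumeration, expression scoring, PTM event attachment, pathway
#' PTM statistics, BH correction (expression and PTM statistics as two
#' families) and selection. Deterministic given `config$seed`.
#'
#' @param expr_matrix Numeric matrix, proteins x samples.
#' @param ptm_matrix Optional numeric matrix, site keys x samples (`NULL` for
#'   an expression-only run).
#' @param design A [cluster_design()].
#' @param bundle A [reference_bundle()].
#' @param config An [inference_config()].
#' @return An object of class `lri_run`: list with `results` (one row per
#'   triple, mirroring the standard output schema), `events` (one row per
#'   observed PTM event, keyed by triple), and `meta` (seed, config, stage
#'   counts).
#' @export
run_differential_pipeline <- function(expr_matrix, ptm_matrix = NULL, design,
                                      bundle,
                                      config = inference_config()) {
  stopifnot(inherits(design, "cluster_design"),
            inherits(bundle, "reference_bundle"))
  rownames(expr_matrix) <- toupper(rownames(expr_matrix))
  counts <- list()

  expr_diff <- differential_table(
    expr_matrix, design,
    test = function(a, b) wilcoxon_two_sided(a, b, config$exact_threshold))
  counts$expr_rows_tested <- sum(!is.na(expr_diff$p_value))

  ptm_diff <- NULL
  if (!is.null(ptm_matrix)) {
    if (!length(intersect(colnames(ptm_matrix), colnames(expr_matrix)))) {
      stop("expression and PTM matrices have disjoint sample sets",
           call. = FALSE)
    }
    norm <- normalize_ptm(ptm_matrix, expr_matrix,
                          mode = config$ptm_normalization)
    ptm_diff <- differential_table(
      norm, design,
      test = function(a, b) wilcoxon_two_sided(a, b, config$exact_threshold))
    if (config$ptm_position_mode == "protein") {
      ptm_diff <- collapse_to_protein_mode(ptm_diff)
    }
    counts$ptm_sites_tested <- sum(!is.na(ptm_diff$p_value))
  }

  expr_rows <- rownames(expr_matrix)
  triples <- enumerate_candidate_triples(bundle, expr_rows, config)
  counts$candidate_triples <- nrow(triples)
  results <- score_triples_expression(triples, expr_diff, config)
  counts$scored_triples <- nrow(results)

  events_list <- vector("list", nrow(results))
  p_ptm <- rep(NA_real_, nrow(results))
  n_ev <- integer(nrow(results))
  n_con <- integer(nrow(results))
  n_dis <- integer(nrow(results))
  if (!is.null(ptm_diff) && nrow(results)) {
    for (i in seq_len(nrow(results))) {
      ev <- attach_ptm_events(results[i, ], bundle$ptm_records, ptm_diff,
                              expr_rows)
      events_list[[i]] <- ev
      n_ev[i] <- nrow(ev)
      n_con[i] <- sum(ev$concordance == "concordant")
      n_dis[i] <- sum(ev$concordance == "discordant")
      p_ptm[i] <- pathway_ptm_pvalue(ev, n_mc = config$n_mc,
                                     seed = config$seed)
    }
  }
  results$n_ptm_events <- n_ev
  results$n_concordant <- n_con
  results$n_discordant <- n_dis
  results$p_ptm_pathway <- p_ptm
  results$q_ptm <- bh_adjust(p_ptm)

  results <- select_lris(results, config)
  counts$selected <- sum(results$selected)

  events <- do.call(rbind, lapply(seq_along(events_list), function(i) {
    ev <- events_list[[i]]
    if (is.null(ev) || !nrow(ev)) return(NULL)
    cbind(data.frame(ligand = results$ligand[i],
                     receptor = results$receptor[i],
                     pathway_id = results$pathway_id[i],
                     stringsAsFactors = FALSE),
          ev)
  }))
  if (is.null(events)) {
    events <- empty_df(ligand = character(), receptor = character(),
                       pathway_id = character(), protein = character(),
                       residue = character(), position = integer(),
                       ptm_type = character(), direction = character(),
                       enzyme = character(), site_key = character(),
                       delta = numeric(), p_value = numeric(),
                       enzyme_detected = logical(),
                       substrate_detected = logical(),
                       concordance = character())
  }

  structure(list(results = results, events = events,
                 meta = list(seed = config$seed, n_mc = config$n_mc,
                             config = unclass(config), counts = counts)),
            class = "lri_run")
}

#' @export
print.lri_run <- function(x, ...) {
  cat("lri_run:", nrow(x$results), "triples scored,",
      sum(x$results$selected), "selected,",
      nrow(x$events), "PTM events (seed", x$meta$seed, ")\n")
  invisible(x)
}
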