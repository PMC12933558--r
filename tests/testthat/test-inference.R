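make_diff <- function(keys, delta, p) {
  data.frame(row_key = keys, delta = delta, p_value = p,
             q_value = bh_adjust(p), stringsAsFactors = FALSE)
}

test_that("enumerate_candidate_triples crosses LR pairs with receptor pathways", {
  b <- tiny_bundle()
  cfg <- inference_config(min_targets = 1L)
  expr_rows <- c("L1", "R1", "K1", "T1", "T2")
  tr <- enumerate_candidate_triples(b, expr_rows, cfg)
  expect_equal(nrow(tr), 1L)
  expect_setequal(tr$targets[[1]], c("K1", "T1", "T2"))
  # ligand must be detected
  expect_equal(nrow(enumerate_candidate_triples(b, c("R1", "K1", "T1"), cfg)),
               0L)
  # min_targets filters the triple out
  cfg5 <- inference_config(min_targets = 5L)
  expect_equal(nrow(enumerate_candidate_triples(b, expr_rows, cfg5)), 0L)
  # a receptor in two pathways yields two triples
  b2 <- suppressMessages(reference_bundle(
    data.frame(ligand = "L1", receptor = "R1", source = "x"),
    list(pathway_def("PA", members = c("R1", "T1")),
         pathway_def("PB", members = c("R1", "T2"))),
    intracellular_network(data.frame(source = c("R1", "R1"),
                                     target = c("T1", "T2"), directed = 1))))
  expect_equal(nrow(enumerate_candidate_triples(b2, c("L1", "R1", "T1", "T2"),
                                                cfg)),
               2L)
})

test_that("score_triples_expression enforces sign constraints without thresholding", {
  b <- tiny_bundle()
  cfg <- inference_config(min_targets = 1L, n_mc = 1000)
  tr <- enumerate_candidate_triples(b, c("L1", "R1", "K1", "T1", "T2"), cfg)
  keys <- c("L1", "R1", "K1", "T1", "T2")
  up <- make_diff(keys, delta = c(2, 1, 1, 1, 1), p = rep(0.5, 5))
  res <- score_triples_expression(tr, up, cfg)
  expect_equal(nrow(res), 1L)
  expect_equal(res$p_overall, res$p_ligand * res$p_receptor * res$p_pathway)
  expect_true(res$q_value >= res$p_overall)
  # ligand down -> removed even if highly significant
  down <- make_diff(keys, delta = c(-2, 1, 1, 1, 1), p = rep(0.001, 5))
  expect_equal(nrow(score_triples_expression(tr, down, cfg)), 0L)
  # inhibitory receptor option keeps negative receptor deltas
  inh <- make_diff(keys, delta = c(2, -1, 1, 1, 1), p = rep(0.5, 5))
  cfg_neg <- inference_config(min_targets = 1L, n_mc = 1000,
                              receptor_sign = "negative")
  expect_equal(nrow(score_triples_expression(tr, inh, cfg_neg)), 1L)
  expect_equal(nrow(score_triples_expression(tr, inh, cfg)), 0L)
  # missing receptor row drops the triple with a log line
  expect_message(
    out <- score_triples_expression(tr, make_diff("L1", 2, 0.5), cfg),
    "dropped")
  expect_equal(nrow(out), 0L)
})

test_that("target_sign positive neutralizes wrong-signed targets", {
  b <- tiny_bundle()
  cfg_any <- inference_config(min_targets = 1L, n_mc = 1000)
  cfg_pos <- inference_config(min_targets = 1L, n_mc = 1000,
                              target_sign = "positive")
  tr <- enumerate_candidate_triples(b, c("L1", "R1", "K1", "T1", "T2"),
                                    cfg_any)
  keys <- c("L1", "R1", "K1", "T1", "T2")
  d <- make_diff(keys, delta = c(2, 1, -1, -1, -1), p = c(0.5, 0.5, 0.001,
                                                          0.001, 0.001))
  p_any <- score_triples_expression(tr, d, cfg_any)$p_pathway
  p_pos <- score_triples_expression(tr, d, cfg_pos)$p_pathway
  expect_lt(p_any, 0.05)
  expect_equal(p_pos, 1)  # all targets wrong-signed -> p = 1 inputs
})

test_that("concordance_flag covers the full direction x sign table", {
  expect_equal(concordance_flag("added", 1.2), "concordant")
  expect_equal(concordance_flag("removed", -0.8), "concordant")
  expect_equal(concordance_flag("added", -2), "discordant")
  expect_equal(concordance_flag("removed", 0.4), "discordant")
  expect_equal(concordance_flag("added", 0), "indeterminate")
  expect_equal(concordance_flag("removed", NA), "indeterminate")
  expect_error(concordance_flag("sideways", 1))
})

test_that("attach_ptm_events requires detection and keeps discordant events", {
  b <- tiny_bundle()
  triple <- list(pathway_id = "P1")
  ptm_diff <- make_diff(c("T1:Y187:phosphorylation", "T2:S10:phosphorylation"),
                        delta = c(1.5, 0.7), p = c(0.01, 0.2))
  ev <- attach_ptm_events(triple, b$ptm_records, ptm_diff,
                          expr_rows = c("T1", "T2", "K1"))
  expect_equal(nrow(ev), 2L)
  # T2 record direction is "removed" but delta > 0 -> discordant, retained
  expect_setequal(ev$concordance, c("concordant", "discordant"))
  expect_true(all(ev$site_key %in% ptm_diff$row_key))
  # enzyme K1 not detected -> no events at all
  expect_equal(nrow(attach_ptm_events(triple, b$ptm_records, ptm_diff,
                                      expr_rows = c("T1", "T2"))),
               0L)
  # substrate not detected -> its event vanishes
  ev2 <- attach_ptm_events(triple, b$ptm_records, ptm_diff,
                           expr_rows = c("T1", "K1"))
  expect_equal(ev2$protein, "T1")
  # events are a subset of the pathway's reference records
  ref_keys <- format_site_key(b$ptm_records$protein, b$ptm_records$residue,
                              b$ptm_records$position, b$ptm_records$ptm_type)
  expect_true(all(ev$site_key %in% ref_keys))
})

test_that("pathway_ptm_pvalue handles empty, single and paired events", {
  empty <- attach_ptm_events(list(pathway_id = "NONE"),
                             tiny_bundle()$ptm_records,
                             make_diff("X:Y1:t", 1, 0.5), "X")
  expect_true(is.na(pathway_ptm_pvalue(empty)))
  one <- data.frame(p_value = 0.02)
  expect_equal(pathway_ptm_pvalue(one, n_mc = 20000, seed = 3), 0.02,
               tolerance = 0.02)
  two <- data.frame(p_value = c(0.1, 0.5))
  expect_equal(pathway_ptm_pvalue(two, n_mc = 4000, seed = 3),
               oracle_rank_pvalue(c(0.1, 0.5), 20000, 99), tolerance = 0.05)
})

test_that("select_lris implements dual-threshold and product selection", {
  base <- data.frame(
    p_overall = c(0.001, 0.2, 0.2, 0.6),
    p_ptm_pathway = c(NA, 0.001, NA, 0.001),
    stringsAsFactors = FALSE)
  base$p_overall_cal <- base$p_overall      # treat as already calibrated
  base$q_value <- base$p_overall
  base$q_ptm <- base$p_ptm_pathway
  out <- select_lris(base, inference_config(n_mc = 1000))
  expect_equal(out$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$selection_reason,
               c("expression_only", "ptm_rescued", "rejected", "rejected"))
  # significant PTM evidence upgrades the reason
  conf <- base[2, ]
  conf$p_overall_cal <- conf$q_value <- 0.01
  expect_equal(select_lris(conf, inference_config(n_mc = 1000))$selection_reason,
               "ptm_confirmed")
  # product mode: joint evidence 0.04 * 0.04 calibrated as a 4-factor product
  pm <- data.frame(p_overall = 0.04, p_ptm_pathway = 0.04)
  pm$p_overall_cal <- calibrate_product(0.04, 3)
  pm$q_value <- pm$p_overall_cal
  pm$q_ptm <- pm$p_ptm_pathway
  sel <- select_lris(pm, inference_config(selection_mode = "product",
                                          n_mc = 1000))
  expect_equal(calibrate_product(0.0016, 4) <= 0.05, sel$selected)
})

test_that("collapse_to_protein_mode broadcasts the most extreme site", {
  d <- make_diff(c("PRT1:S10:phosphorylation", "PRT1:Y20:phosphorylation",
                   "PRT2:S5:phosphorylation"),
                 delta = c(1, -2, 0.5), p = c(0.3, 0.001, 0.8))
  out <- collapse_to_protein_mode(d)
  expect_equal(out$p_value[1:2], c(0.001, 0.001))
  expect_equal(out$delta[1:2], c(-2, -2))
  expect_equal(out$p_value[3], 0.8)  # single-site protein unchanged
  expect_identical(collapse_to_protein_mode(out)[1:3],
                   out[1:3])  # idempotent on delta/p columns
  # tie on p -> larger |delta| wins; tie again -> smallest site key
  t1 <- make_diff(c("X:A1:t", "X:B2:t"), delta = c(1, -3), p = c(0.1, 0.1))
  expect_equal(collapse_to_protein_mode(t1)$delta, c(-3, -3))
  t2 <- make_diff(c("X:B2:t", "X:A1:t"), delta = c(1, 1), p = c(0.1, 0.1))
  out2 <- collapse_to_protein_mode(t2)
  expect_equal(out2$delta, c(1, 1))
  # winner is the lexicographically smallest key (X:A1:t), same stats here
})

test_that("pipeline recovers a planted triple and is PTM-invariant on expression", {
  x <- sim_run(seed = 31)
  res <- x$run$results
  planted <- res$pathway_id == x$sim$truth$planted_triples$pathway_id
  expect_true(any(planted))
  expect_true(res$selected[planted])
  expect_equal(res$selection_reason[planted], "ptm_confirmed")
  expect_lt(res$p_overall[planted], 1e-4)
  # expression columns identical with and without the PTM matrix
  run_noptm <- suppressMessages(run_differential_pipeline(
    x$mats$expr, NULL, x$mats$design, x$sim$bundle,
    inference_config(n_mc = 1000, seed = 31,
                     ptm_normalization = "difference")))
  cols <- c("ligand", "receptor", "pathway_id", "p_ligand", "p_receptor",
            "p_pathway", "p_overall", "q_value")
  expect_identical(res[cols], run_noptm$results[cols])
  expect_true(all(is.na(run_noptm$results$p_ptm_pathway)))
  expect_equal(run_noptm$results$n_ptm_events,
               rep(0L, nrow(run_noptm$results)))
  # every selected row satisfies the selection predicate
  cfg <- inference_config(n_mc = 1000, seed = 31,
                          ptm_normalization = "difference")
  pass_expr <- res$q_value <= cfg$alpha_expr
  ptm_ok <- !is.na(res$q_ptm) & res$q_ptm <= cfg$alpha_ptm
  predicted <- pass_expr |
    (res$q_value <= cfg$alpha_expr_relaxed & ptm_ok)
  expect_identical(res$selected, predicted)
})

test_that("pipeline in protein mode still finds the planted triple", {
  cfg <- sim_config(seed = 13)
  sim <- simulate_bundle(cfg)
  mats <- simulate_matrices(sim$bundle, sim$truth, cfg)
  run <- suppressMessages(run_differential_pipeline(
    mats$expr, mats$ptm, mats$design, sim$bundle,
    inference_config(n_mc = 1000, seed = 13, ptm_normalization = "difference",
                     ptm_position_mode = "protein")))
  expect_gte(score_recovery(run, sim$truth)[["sensitivity"]], 1)
})

test_that("disjoint sample sets between matrices are fatal", {
  x <- sim_run(seed = 3, n_pathways = 2, n_ligands = 2, n_receptors = 2)
  bad_ptm <- x$mats$ptm
  colnames(bad_ptm) <- paste0("zz", seq_len(ncol(bad_ptm)))
  expect_error(run_differential_pipeline(x$mats$expr, bad_ptm, x$mats$design,
                                         x$sim$bundle,
                                         inference_config(n_mc = 1000)),
               "disjoint")
})
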