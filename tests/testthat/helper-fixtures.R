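# Fixtures are built in code at test time; nothing binary ships with the
# package.

# Minimal bundle: 2 LR pairs, 1 pathway (R1 -> K1 -> T1/T2 chain), 3 edges,
# 2 PTM records.
tiny_bundle <- function() {
  suppressMessages(reference_bundle(
    lr_pairs = data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                          source = "fixture", stringsAsFactors = FALSE),
    pathways = list(pathway_def("P1", "pathway one", "user",
                                c("R1", "K1", "T1", "T2"))),
    network = intracellular_network(data.frame(
      source = c("R1", "K1", "K1"), target = c("K1", "T1", "T2"),
      directed = 1L, stringsAsFactors = FALSE)),
    ptm_records = data.frame(
      protein = c("T1", "T2"), residue = c("Y", "S"),
      position = c(187L, 10L), ptm_type = "phosphorylation",
      direction = c("added", "removed"), enzyme = "K1", pathway_id = "P1",
      stringsAsFactors = FALSE)))
}

# A reaction entity in the JSON-shaped structure.
rx_entity <- function(protein, mods = list(), complex_size = NULL) {
  list(protein = protein, complex_id = NULL,
       complex_size = complex_size,
       mods = lapply(mods, function(m) {
         list(residue = m[[1]], position = as.integer(m[[2]]),
              ptm_type = m[[3]])
       }))
}

rx <- function(id, inputs, outputs, catalysts = character(0),
               pathway_ids = character(0), is_candidate = FALSE) {
  list(reaction_id = id, is_candidate = is_candidate,
       pathway_ids = as.list(pathway_ids), catalysts = as.list(catalysts),
       inputs = inputs, outputs = outputs)
}

# The golden 3-reaction fixture: one candidate (excluded), one without state
# change, one yielding exactly one record.
golden_reactions <- function() {
  list(
    rx("RX1", list(rx_entity("AAA")), list(rx_entity("AAA", list(list("S", 5, "phosphorylation")))),
       catalysts = "KIN1", pathway_ids = "PW1", is_candidate = TRUE),
    rx("RX2", list(rx_entity("BBB", list(list("T", 7, "phosphorylation")))),
       list(rx_entity("BBB", list(list("T", 7, "phosphorylation")))),
       catalysts = "KIN2", pathway_ids = "PW1"),
    rx("RX3", list(rx_entity("MAPK1")),
       list(rx_entity("MAPK1", list(list("Y", 187, "phosphorylation")))),
       catalysts = "KIN3", pathway_ids = "PW1"))
}

random_reactions <- function(n, seed) {
  set.seed(seed)
  proteins <- c("P1", "P2", "P3")
  rand_mods <- function() {
    k <- sample(0:3, 1)
    lapply(seq_len(k), function(i) {
      list(sample(c("S", "T", "Y"), 1), sample(1:20, 1), "phosphorylation")
    })
  }
  lapply(seq_len(n), function(i) {
    side <- function() {
      lapply(seq_len(sample(1:2, 1)), function(j) {
        rx_entity(sample(proteins, 1), rand_mods(),
                  complex_size = sample(c(NA, 2L, 10L, 11L, 15L), 1))
      })
    }
    rx(paste0("R", i), side(), side(),
       catalysts = sample(c("K1", "K2"), sample(0:2, 1)),
       pathway_ids = sample(c("PWA", "PWB"), sample(0:2, 1)),
       is_candidate = stats::runif(1) < 0.2)
  })
}

# PhosphoSitePlus-dialect flat file writer (3 preamble lines, then header).
psp_headers <- list(
  regulatory = c("GENE", "PROTEIN", "ORGANISM", "MOD_RSD", "SITE_GRP_ID",
                 "DOMAIN", "ON_FUNCTION", "ON_PROCESS", "ON_PROT_INTERACT",
                 "NOTES"),
  kinase_substrate = c("GENE", "KINASE", "KIN_ORGANISM", "SUBSTRATE",
                       "SUB_GENE", "SUB_ORGANISM", "SUB_MOD_RSD",
                       "SITE_GRP_ID", "DOMAIN"),
  disease = c("DISEASE", "ALTERATION", "GENE", "PROTEIN", "ORGANISM",
              "MOD_RSD", "SITE_GRP_ID", "NOTES"))

psp_fixture_rows <- function() {
  list(
    regulatory = list(
      list(GENE = "MAPK1", PROTEIN = "MAPK1", ORGANISM = "human",
           MOD_RSD = "Y187-p", SITE_GRP_ID = "447543", DOMAIN = "Pkinase",
           ON_FUNCTION = "activity, induced", ON_PROCESS = "cell growth",
           NOTES = "activation loop"),
      list(GENE = "STAT3", PROTEIN = "STAT3", ORGANISM = "human",
           MOD_RSD = "Y705-p", SITE_GRP_ID = "448192", DOMAIN = "SH2",
           ON_FUNCTION = "activity, induced", ON_PROCESS = "transcription",
           NOTES = ""),
      list(GENE = "MOUSEONLY", PROTEIN = "MOUSEONLY", ORGANISM = "mouse",
           MOD_RSD = "S5-p", SITE_GRP_ID = "1", DOMAIN = "", ON_FUNCTION = "",
           ON_PROCESS = "", NOTES = "")),
    kinase_substrate = list(
      list(GENE = "MAP2K1", KINASE = "MEK1", KIN_ORGANISM = "human",
           SUBSTRATE = "MAPK1", SUB_GENE = "MAPK1", SUB_ORGANISM = "human",
           SUB_MOD_RSD = "Y187", SITE_GRP_ID = "447543", DOMAIN = "Pkinase")),
    disease = list(
      list(DISEASE = "lung cancer", ALTERATION = "increased", GENE = "MAPK1",
           PROTEIN = "MAPK1", ORGANISM = "human", MOD_RSD = "Y187-p",
           SITE_GRP_ID = "447543", NOTES = "dysregulated in tumors")))
}

write_psp_fixture <- function(path, kind, rows, gz = FALSE) {
  hdr <- psp_headers[[kind]]
  lines <- c("Synthetic fixture in the PhosphoSitePlus flat-file dialect.",
             "Not real database content.",
             "",
             paste(hdr, collapse = "\t"),
             vapply(rows, function(r) {
               paste(vapply(hdr, function(h) as.character(r[[h]] %||% ""), ""),
                     collapse = "\t")
             }, ""))
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quick pipeline run on simulated data with a small Monte-Carlo size.
sim_run <- function(seed, n_mc = 1000, effect_size = 3, n_planted = 1,
                    frac_concordant = 1, ...) {
  cfg <- sim_config(seed = seed, effect_size = effect_size,
                    n_planted = n_planted, frac_concordant = frac_concordant,
                    ...)
  sim <- simulate_bundle(cfg)
  mats <- simulate_matrices(sim$bundle, sim$truth, cfg)
  run <- suppressMessages(run_differential_pipeline(
    mats$expr, mats$ptm, mats$design, sim$bundle,
    inference_config(n_mc = n_mc, seed = seed,
                     ptm_normalization = "difference")))
  list(run = run, sim = sim, mats = mats, cfg = cfg)
}
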