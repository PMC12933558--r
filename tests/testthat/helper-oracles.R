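# Independent oracles. These deliberately avoid the package's own code paths:
# brute-force enumeration, textbook formulas, and a separately coded
# Monte-Carlo sampler.

# Exact two-sided rank-sum p by enumerating every assignment of the observed
# rank multiset to the first group (valid for tie-free data).
oracle_wilcoxon_exact <- function(a, b) {
  r <- rank(c(a, b))
  n <- length(a)
  m <- length(b)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  us <- apply(utils::combn(n + m, n), 2L,
              function(i) sum(r[i]) - n * (n + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Textbook step-up BH by explicit loop.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[ord[i]] * n / i, 1)
    adj_sorted[i] <- running
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# Breadth-first reachability over a raw edge table (directed edges forward,
# undirected both ways), restricted to pathway members.
oracle_reachable <- function(edges, members, receptor) {
  e <- edges[edges$source %in% members & edges$target %in% members, ,
             drop = FALSE]
  und <- e[!as.logical(e$directed), , drop = FALSE]
  arcs <- rbind(e[c("source", "target")],
                data.frame(source = und$target, target = und$source))
  seen <- receptor
  frontier <- receptor
  repeat {
    nxt <- setdiff(unique(arcs$target[arcs$source %in% frontier]), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(setdiff(seen, receptor))
}

# Rank statistic computed from first principles (no shared code), calibrated
# with its own sampler.
oracle_rank_stat <- function(pvals) {
  n <- length(pvals)
  s <- sort(pvals)
  min(vapply(seq_len(n), function(k) stats::pbeta(s[k], k, n - k + 1), 0))
}

oracle_rank_pvalue <- function(pvals, n_mc, seed) {
  set.seed(seed)
  n <- length(pvals)
  null <- replicate(n_mc, oracle_rank_stat(stats::runif(n)))
  (1 + sum(null <= oracle_rank_stat(pvals))) / (n_mc + 1)
}

# Expected PTM reference records by independent nested loops over a reaction
# list (same JSON-shaped structure the builder consumes).
oracle_builder_keys <- function(reactions, max_complex_size) {
  keys <- character(0)
  for (r in reactions) {
    if (isTRUE(r$is_candidate)) next
    side_mods <- function(entities) {
      out <- list()
      for (e in entities) {
        cs <- e$complex_size
        if (!is.null(cs) && !is.na(cs) && cs > max_complex_size) next
        p <- toupper(e$protein)
        for (m in e$mods) {
          out[[length(out) + 1L]] <- paste(p, toupper(m$residue), m$position,
                                           m$ptm_type, sep = "|")
        }
      }
      unique(unlist(out))
    }
    inm <- side_mods(r$inputs)
    outm <- side_mods(r$outputs)
    # keys embed the protein, so a global set difference equals the
    # per-protein diff after union-by-protein (length guards: paste0 pads
    # zero-length arguments to length 1)
    add <- setdiff(outm, inm)
    rem <- setdiff(inm, outm)
    diffs <- c(if (length(add)) paste0(add, "|added"),
               if (length(rem)) paste0(rem, "|removed"))
    cats <- if (length(r$catalysts)) toupper(unlist(r$catalysts)) else ""
    pws <- if (length(r$pathway_ids)) unlist(r$pathway_ids) else "UNASSIGNED"
    for (d in diffs) for (cz in cats) for (pw in pws) {
      keys <- c(keys, paste(d, cz, pw, sep = "|"))
    }
  }
  unique(keys)
}

record_keys <- function(records) {
  paste(records$protein, records$residue, records$position, records$ptm_type,
        records$direction, records$enzyme, records$pathway_id, sep = "|")
}
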