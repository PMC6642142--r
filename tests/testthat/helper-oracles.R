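`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive results from first principles (nested loops,
# full enumeration) and share no code with the package internals.

# gap between two 0-based half-open intervals; 0 if they overlap
oracle_gap <- function(s1, e1, s2, e2) max(0, max(s1, s2) - min(e1, e2))

# all-pairs proximity scan
oracle_proximity <- function(lnc, mrna, window) {
  out <- NULL
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(mrna))) {
      if (lnc$chrom[i] != mrna$chrom[j]) next
      d <- oracle_gap(lnc$start[i], lnc$end[i], mrna$start[j], mrna$end[j])
      if (d < window) {
        out <- rbind(out, data.frame(lnc_id = lnc$id[i], mrna_id = mrna$id[j],
                                     distance_bp = d, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(lnc_id = character(), mrna_id = character(),
                      distance_bp = numeric(), stringsAsFactors = FALSE)
  }
  out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
}

# all-pairs opposite-strand overlap scan
oracle_antisense <- function(lnc, mrna) {
  out <- NULL
  for (i in seq_len(nrow(lnc))) {
    for (j in seq_len(nrow(mrna))) {
      if (lnc$chrom[i] != mrna$chrom[j]) next
      if (!(lnc$strand[i] %in% c("+", "-")) || !(mrna$strand[j] %in% c("+", "-"))) next
      if (lnc$strand[i] == mrna$strand[j]) next
      if (lnc$start[i] < mrna$end[j] && mrna$start[j] < lnc$end[i]) {
        out <- rbind(out, data.frame(lnc_id = lnc$id[i], mrna_id = mrna$id[j],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(lnc_id = character(), mrna_id = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
}

# triple-loop DE-gated triad enumeration
oracle_triads <- function(lnc_set, mirna_de, mrna_de, binding, targets,
                          direction) {
  mir_dir <- if (direction == "up") "down" else "up"
  bkey <- paste(binding$source_id, binding$target_id)
  tkey <- paste(targets$source_id, targets$target_id)
  out <- NULL
  for (L in lnc_set) {
    for (mi in seq_len(nrow(mirna_de))) {
      M <- mirna_de$feature_id[mi]
      if (mirna_de$direction[mi] != mir_dir) next
      if (!(paste(L, M) %in% bkey)) next
      for (gi in seq_len(nrow(mrna_de))) {
        G <- mrna_de$feature_id[gi]
        if (mrna_de$direction[gi] != direction) next
        if (!(paste(M, G) %in% tkey)) next
        out <- rbind(out, data.frame(lnc_id = L, mirna_id = M, mrna_id = G,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# hypergeometric right tail by full enumeration of all C(N, n) draws
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)     # items 1..K are "in the set"
  mean(hits >= k)
}

# Dunn pairwise p by exhaustive enumeration of group assignments. The
# pooled midranks are fixed under permutation of labels, and the pair
# statistic only depends on which elements land in the two compared groups,
# so the enumeration walks all (g_a, g_b) subsets; the remaining elements
# form the third group.
oracle_dunn_perm_p <- function(groups, pair) {
  x <- unlist(groups, use.names = FALSE)
  r <- rank(x)
  labs <- rep(names(groups), vapply(groups, length, 0L))
  n_a <- length(groups[[pair[1]]]); n_b <- length(groups[[pair[2]]])
  obs <- abs(mean(r[labs == pair[1]]) - mean(r[labs == pair[2]]))
  idx <- seq_along(x)
  count <- 0L; total <- 0L
  for (ga in utils::combn(idx, n_a, simplify = FALSE)) {
    rest <- setdiff(idx, ga)
    sa <- sum(r[ga]) / n_a
    for (gb in utils::combn(rest, n_b, simplify = FALSE)) {
      total <- total + 1L
      if (abs(sa - sum(r[gb]) / n_b) >= obs - 1e-12) count <- count + 1L
    }
  }
  count / total
}

# BH step-up applied literally from its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# convenience: run the full DE -> gates -> triads chain on a simulation
run_recovery <- function(sim) {
  lnc_de <- ttest_de(quantile_normalize(sim$lnc_expr))
  mrna_de <- ttest_de(quantile_normalize(sim$mrna_expr))
  mir_de <- nb_exact_de(sim$mirna_counts)
  wl <- sim$features$id[sim$features$type == "gene" &
                          sim$features$biotype == "lncRNA"]
  fw <- build_sponge_triads(
    select_sponge_lncrnas(lnc_de, "up", whitelist = wl),
    mir_de, mrna_de, sim$tables$binding, sim$tables$targets, "up",
    lnc_de = lnc_de)
  rv <- build_sponge_triads(
    select_sponge_lncrnas(lnc_de, "down", intensity_min = 0),
    mir_de, mrna_de, sim$tables$binding, sim$tables$targets, "down",
    lnc_de = lnc_de)
  got <- paste(c(fw$lnc_id, rv$lnc_id), c(fw$mirna_id, rv$mirna_id),
               c(fw$mrna_id, rv$mrna_id))
  tru <- paste(sim$truth$planted_triads$lnc_id,
               sim$truth$planted_triads$mirna_id,
               sim$truth$planted_triads$mrna_id)
  list(forward = fw, reverse = rv, got = got, truth = tru,
       precision = if (length(got)) mean(got %in% tru) else NA_real_,
       recall = mean(tru %in% got),
       lnc_de = lnc_de, mrna_de = mrna_de, mir_de = mir_de)
}
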