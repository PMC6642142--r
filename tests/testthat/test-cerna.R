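mk_de2 <- function(ids, fc, p = 0.01, intensity = 200) {
  structure(data.frame(
    feature_id = ids, mean_ctrl = intensity, mean_trt = intensity,
    signed_fc = fc, statistic = 0, p = p, q = p, raw_intensity = intensity,
    direction = ifelse(abs(fc) >= 1.5 & p <= 0.05,
                       ifelse(fc > 0, "up", "down"), "flat"),
    stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
}

test_that("sponge lncRNA selection gates on direction, intensity and whitelist", {
  de <- mk_de2(c("L1", "L2", "L3", "L4"), c(2, 2, 2, 1.1),
               intensity = c(150, 100, 150, 900))
  # strict > 100: L2 at exactly 100 is rejected
  expect_identical(select_sponge_lncrnas(de, "up", whitelist = c("L1", "L2", "L4")),
                   "L1")
  # whitelisted but non-significant is rejected
  expect_false("L4" %in% select_sponge_lncrnas(de, "up", whitelist = c("L1", "L4")))
  # no whitelist -> annotation gate off
  expect_setequal(select_sponge_lncrnas(de, "up"), c("L1", "L3"))
})

test_that("triad construction applies every DE gate", {
  mir <- mk_de2(c("M1", "M2"), c(-2.9, 2))
  mrna <- mk_de2(c("G1", "G2"), c(2, -2))
  bind <- interaction_table(c("L1", "L1"), c("M1", "M2"), c(2L, 3L),
                            "lnc_mirna_binding")
  targ <- interaction_table(c("M1", "M1", "M2"), c("G1", "G2", "G1"),
                            rep("validated", 3), "mirna_mrna_target")
  tri <- build_sponge_triads("L1", mir, mrna, bind, targ, "up",
                             lnc_de = mk_de2("L1", 1.7))
  # only (L1, M1, G1) survives: M2 is up (wrong direction), G2 is down
  expect_equal(nrow(tri), 1)
  expect_identical(unlist(tri[1, c("lnc_id", "mirna_id", "mrna_id")],
                          use.names = FALSE), c("L1", "M1", "G1"))
  expect_equal(tri$binding_sites, 2L)
  expect_equal(tri$mirna_fc, -2.9)
  # empty binding table -> zero triads
  empty <- interaction_table(character(), character(), integer(),
                             "lnc_mirna_binding")
  expect_equal(nrow(build_sponge_triads("L1", mir, mrna, empty, targ, "up")), 0)
  # mixed-up table kinds are an error
  expect_error(build_sponge_triads("L1", mir, mrna, targ, targ, "up"), "kind")
})

test_that("published forward-table triads contain the printed worked example", {
  fx <- sponge_fixture("forward")
  hit <- fx$triads[fx$triads$lnc_id == "ENST00000585387" &
                     fx$triads$mirna_id == "hsa-miR-185-5p" &
                     fx$triads$mrna_id == "BAK1", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$binding_sites, 2L)
  expect_equal(hit$lnc_fc, 1.735)
  expect_equal(hit$mirna_fc, -2.865)
})

test_that("assembled fixture networks reproduce the published node counts", {
  fw <- sponge_fixture("forward")
  net_f <- assemble_network(triads_forward = fw$triads)
  cls_f <- table(net_f$nodes$class)
  expect_equal(unname(cls_f["lncRNA"]), 10)  # 10 sponge lncRNAs
  expect_equal(unname(cls_f["miRNA"]), 12)   # 12 down-regulated miRNAs
  expect_equal(unname(cls_f["mRNA"]), 134)   # 134 targeted mRNAs

  rv <- sponge_fixture("reverse")
  net_r <- assemble_network(triads_reverse = rv$triads)
  cls_r <- table(net_r$nodes$class)
  expect_equal(unname(cls_r["miRNA"]), 7)    # 7 up-regulated miRNAs
  # 21 printed lncRNA-miRNA pairs over 16 distinct lncRNAs
  expect_equal(sum(net_r$edges$edge_type == "lnc_mirna"), 21)
  expect_equal(unname(cls_r["lncRNA"]), 16)
  expect_equal(sum(net_r$edges$edge_type == "mirna_mrna"), 131)
})

test_that("a single triad gives 3 nodes and 2 edges; stats recount the graph", {
  tri <- triads_from_pair_table(
    data.frame(lncrna_id = "L1", lnc_fc = 2, lnc_p = 0.01, mirna_id = "M1",
               binding_sites = 4L, mirna_fc = -2, mirna_p = 0.01,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = "M1", mrna_id = "G1", stringsAsFactors = FALSE),
    "forward")
  net <- assemble_network(triads_forward = tri)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  st <- network_stats(net)
  expect_true(all(st$degree[st$class != "miRNA"] == 1))
  expect_equal(st$degree[st$class == "miRNA"], 2)
  expect_equal(st$total_binding_sites[st$class == "lncRNA"], 4L)
  expect_equal(st$distinct_targets[st$class == "miRNA"], 1L)
})

test_that("network stats equal a brute-force recount on random networks", {
  for (seed in c(71, 72)) {
    sim <- simulate_study(sim_config(n_coding = 60, n_lnc = 40, n_mirna = 40,
                                     seed = seed))
    rec <- run_recovery(sim)
    net <- assemble_network(rec$forward, rec$reverse)
    st <- network_stats(net)
    ek <- rbind(data.frame(a = net$edges$source, b = net$edges$target))
    for (i in seq_len(nrow(st))) {
      expect_equal(st$degree[i], sum(ek$a == st$id[i]) + sum(ek$b == st$id[i]))
    }
    lnc_e <- net$edges[net$edges$edge_type == "lnc_mirna", ]
    for (L in st$id[st$class == "lncRNA"]) {
      expect_equal(st$total_binding_sites[st$id == L],
                   sum(lnc_e$attribute[lnc_e$source == L]))
    }
  }
})

test_that("direction-inconsistent triads are rejected at assembly", {
  bad <- triads_from_pair_table(
    data.frame(lncrna_id = "L1", lnc_fc = -2, lnc_p = 0.01, mirna_id = "M1",
               binding_sites = 1L, mirna_fc = -2, mirna_p = 0.01,
               stringsAsFactors = FALSE),
    data.frame(mirna_id = "M1", mrna_id = "G1", stringsAsFactors = FALSE),
    "forward")
  expect_error(assemble_network(triads_forward = bad), "inconsistent")
})

test_that("gate tightening is monotone: raising gates never adds a triad", {
  sim <- simulate_study(sim_config(n_coding = 60, n_lnc = 40, n_mirna = 40,
                                   background_density = 0.02, seed = 77))
  lnc_de <- ttest_de(quantile_normalize(sim$lnc_expr))
  mrna_de <- ttest_de(quantile_normalize(sim$mrna_expr))
  mir_de <- nb_exact_de(sim$mirna_counts)
  wl <- sim$features$id[sim$features$type == "gene" &
                          sim$features$biotype == "lncRNA"]
  key <- function(t) paste(t$lnc_id, t$mirna_id, t$mrna_id)
  base <- build_sponge_triads(
    select_sponge_lncrnas(lnc_de, "up", intensity_min = 100, whitelist = wl),
    mir_de, mrna_de, sim$tables$binding, sim$tables$targets, "up")
  for (gate in c(500, 2000)) {
    tighter <- build_sponge_triads(
      select_sponge_lncrnas(lnc_de, "up", intensity_min = gate, whitelist = wl),
      mir_de, mrna_de, sim$tables$binding, sim$tables$targets, "up")
    expect_true(all(key(tighter) %in% key(base)))
  }
  smaller_wl <- wl[seq_len(length(wl) %/% 2)]
  shrunk <- build_sponge_triads(
    select_sponge_lncrnas(lnc_de, "up", intensity_min = 100, whitelist = smaller_wl),
    mir_de, mrna_de, sim$tables$binding, sim$tables$targets, "up")
  expect_true(all(key(shrunk) %in% key(base)))
})

test_that("planted triads are recovered with the brute-force oracle agreeing", {
  sim <- simulate_study(sim_config(seed = 79))
  rec <- run_recovery(sim)
  expect_equal(rec$precision, 1)
  expect_equal(rec$recall, 1)
  # triple-loop oracle equivalence for the forward direction
  wl <- sim$features$id[sim$features$type == "gene" &
                          sim$features$biotype == "lncRNA"]
  sel <- select_sponge_lncrnas(rec$lnc_de, "up", whitelist = wl)
  want <- oracle_triads(sel, rec$mir_de, rec$mrna_de,
                        as.data.frame(sim$tables$binding),
                        as.data.frame(sim$tables$targets), "up")
  got <- rec$forward
  expect_setequal(paste(got$lnc_id, got$mirna_id, got$mrna_id),
                  if (is.null(want)) character() else
                    paste(want$lnc_id, want$mirna_id, want$mrna_id))
  # forward and reverse triad sets are disjoint by construction
  expect_length(intersect(paste(rec$forward$lnc_id, rec$forward$mirna_id,
                                rec$forward$mrna_id),
                          paste(rec$reverse$lnc_id, rec$reverse$mirna_id,
                                rec$reverse$mrna_id)), 0)
})

test_that("edges whose endpoint fails a DE gate never enter a triad", {
  sim <- simulate_study(sim_config(n_coding = 60, n_lnc = 40, n_mirna = 40,
                                   background_density = 0.05, seed = 83))
  rec <- run_recovery(sim)
  up_l <- rec$lnc_de$feature_id[rec$lnc_de$direction == "up"]
  dn_l <- rec$lnc_de$feature_id[rec$lnc_de$direction == "down"]
  dn_m <- rec$mir_de$feature_id[rec$mir_de$direction == "down"]
  up_m <- rec$mir_de$feature_id[rec$mir_de$direction == "up"]
  expect_true(all(rec$forward$lnc_id %in% up_l))
  expect_true(all(rec$forward$mirna_id %in% dn_m))
  expect_true(all(rec$reverse$lnc_id %in% dn_l))
  expect_true(all(rec$reverse$mirna_id %in% up_m))
})
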