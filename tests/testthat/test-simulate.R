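small_cfg <- function(seed = 1, ...) {
  sim_config(n_coding = 40, n_lnc = 24, n_mirna = 30, seed = seed, ...)
}

test_that("same seed gives byte-identical simulation output", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_study(small_cfg(seed = 9)), d1)
  write_simulation(simulate_study(small_cfg(seed = 9)), d2)
  files <- sort(list.files(d1))
  expect_identical(files, sort(list.files(d2)))
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  d3 <- withr::local_tempdir()
  write_simulation(simulate_study(small_cfg(seed = 10)), d3)
  expect_false(identical(readBin(file.path(d1, "lnc_expression.tsv"), "raw", 1e7),
                         readBin(file.path(d3, "lnc_expression.tsv"), "raw", 1e7)))
})

test_that("planted annotation layout matches its truth records", {
  ann <- gen_annotation(small_cfg(seed = 3))
  ft <- ann$features; tr <- ann$truth
  genes <- ft[ft$type == "gene", ]
  expect_true(all(tr$proximity_pairs$lnc_id %in% genes$id))
  # recorded planted distances are exact interval gaps
  for (i in seq_len(nrow(tr$proximity_pairs))) {
    l <- genes[genes$id == tr$proximity_pairs$lnc_id[i], ]
    m <- genes[genes$id == tr$proximity_pairs$mrna_id[i], ]
    expect_equal(oracle_gap(l$start, l$end, m$start, m$end),
                 tr$proximity_pairs$distance_bp[i])
  }
  # antisense pairs overlap their host gene span on the opposite strand;
  # natural-antisense ones additionally intersect an exon
  exons <- ft[ft$type == "exon", ]
  for (i in seq_len(nrow(tr$antisense_pairs))) {
    l <- genes[genes$id == tr$antisense_pairs$lnc_id[i], ]
    h <- genes[genes$id == tr$antisense_pairs$mrna_id[i], ]
    expect_true(l$start < h$end && h$start < l$end && h$strand != l$strand)
    if (tr$classes[l$id] == "natural_antisense") {
      e <- exons[exons$gene_id == h$id, ]
      expect_true(any(l$start < e$end & e$start < l$end))
    }
  }
})

test_that("genome-context classification recovers every planted class label", {
  for (seed in c(1, 2, 3)) {
    ann <- gen_annotation(small_cfg(seed = seed))
    expect_identical(classify_lncrnas(ann$features)[names(ann$truth$classes)],
                     ann$truth$classes)
  }
})

test_that("noiseless expression reproduces planted ratios exactly", {
  cfg <- small_cfg(seed = 5, noise_sd = 0)
  ann <- gen_annotation(cfg)
  m <- gen_expression(cfg, ann$truth, "lnc")
  g <- sample_groups(m)
  ratio <- rowMeans(m[, g != "control"]) / rowMeans(m[, g == "control"])
  expect_equal(unname(ratio), unname(ann$truth$de$lnc$ratio[rownames(m)]),
               tolerance = 1e-12)
})

test_that("planted strong effects are recovered as significant by the t-test", {
  cfg <- small_cfg(seed = 7, noise_sd = 0.25)
  ann <- gen_annotation(cfg)
  de <- ttest_de(gen_expression(cfg, ann$truth, "mrna"))
  planted4 <- names(which(abs(log2(ann$truth$de$mrna$ratio)) == 2))
  expect_true(all(de$p[match(planted4, de$feature_id)] <= 0.05))
})

test_that("miRNA counts follow the mean/dispersion NB parameterization", {
  # phi -> 0 approximates Poisson: variance ~ mean
  cfg <- sim_config(n_coding = 10, n_lnc = 10, n_mirna = 2000, n_per_group = 50,
                    effect_grid = 1, nb_dispersion = 1e-8, lib_size = 2e5,
                    seed = 2)
  cnt <- gen_mirna_counts(cfg, gen_annotation(cfg)$truth)
  mu <- rowMeans(cnt); v <- apply(cnt, 1, var)
  keep <- mu > 50
  expect_gt(sum(keep), 500)
  expect_equal(median(v[keep] / mu[keep]), 1, tolerance = 0.1)

  # with phi = 0.25 the NB quadratic term dominates: var/mu ~ 1 + phi * mu
  cfg2 <- sim_config(n_coding = 10, n_lnc = 10, n_mirna = 2000, n_per_group = 50,
                     effect_grid = 1, nb_dispersion = 0.25, lib_size = 2e5,
                     seed = 2)
  cnt2 <- gen_mirna_counts(cfg2, gen_annotation(cfg2)$truth)
  mu2 <- rowMeans(cnt2); v2 <- apply(cnt2, 1, var)
  keep2 <- mu2 > 50
  expect_equal(median((v2[keep2] - mu2[keep2]) / mu2[keep2]^2), 0.25,
               tolerance = 0.2)
})

test_that("planted down-miRNAs come out with negative signed fold change", {
  cfg <- small_cfg(seed = 4)
  ann <- gen_annotation(cfg)
  de <- nb_exact_de(gen_mirna_counts(cfg, ann$truth))
  down4 <- names(which(ann$truth$de$mirna$ratio == 1 / max(cfg$effect_grid)))
  expect_true(all(de$signed_fc[match(down4, de$feature_id)] < 0))
})

test_that("planted truth is internally consistent", {
  tr <- gen_annotation(small_cfg(seed = 8))$truth
  ratio <- function(type, ids) tr$de[[type]]$ratio[ids]
  fw <- tr$planted_triads[tr$planted_triads$direction == "forward", ]
  rv <- tr$planted_triads[tr$planted_triads$direction == "reverse", ]
  expect_true(all(ratio("lnc", fw$lnc_id) > 1))
  expect_true(all(ratio("mirna", fw$mirna_id) < 1))
  expect_true(all(ratio("mrna", fw$mrna_id) > 1))
  expect_true(all(ratio("lnc", rv$lnc_id) < 1))
  expect_true(all(ratio("mirna", rv$mirna_id) > 1))
  expect_true(all(ratio("mrna", rv$mrna_id) < 1))
  sim <- simulate_study(small_cfg(seed = 8))
  expect_true(all(tr$planted_triads$lnc_id %in% rownames(sim$lnc_expr)))
  expect_true(all(tr$planted_triads$mrna_id %in% rownames(sim$mrna_expr)))
  expect_true(all(tr$planted_triads$mirna_id %in% rownames(sim$mirna_counts)))
})

test_that("interaction tables contain every planted edge plus only eligible decoys", {
  cfg <- small_cfg(seed = 6, background_density = 0.05)
  ann <- gen_annotation(cfg)
  tabs <- gen_interactions(cfg, ann$truth)
  tri <- ann$truth$planted_triads
  bkey <- paste(tabs$binding$source_id, tabs$binding$target_id)
  expect_true(all(paste(tri$lnc_id, tri$mirna_id) %in% bkey))
  tkey <- paste(tabs$targets$source_id, tabs$targets$target_id)
  expect_true(all(paste(tri$mirna_id, tri$mrna_id) %in% tkey))
  # decoy edges never connect two DE features
  de_lnc <- c(ann$truth$de_lnc_up, ann$truth$de_lnc_down)
  de_mir <- c(ann$truth$de_mirna_up, ann$truth$de_mirna_down)
  decoy <- !(bkey %in% paste(tri$lnc_id, tri$mirna_id))
  expect_false(any(tabs$binding$source_id[decoy] %in% de_lnc &
                     tabs$binding$target_id[decoy] %in% de_mir))
  # planted co-expression r values sit in the reference band
  prox_key <- paste(ann$truth$proximity_pairs$lnc_id,
                    ann$truth$proximity_pairs$mrna_id)
  ckey <- paste(tabs$coexpression$source_id, tabs$coexpression$target_id)
  planted_r <- tabs$coexpression$r[ckey %in% prox_key]
  expect_true(all(abs(planted_r) >= 0.6 & abs(planted_r) <= 0.8))
})
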