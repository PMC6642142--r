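test_that("quantile normalization matches the sorted-row-mean definition", {
  # identical columns are a fixed point
  x <- matrix(c(5, 1, 3, 5, 1, 3), 3, 2, dimnames = list(letters[1:3], c("s1", "s2")))
  expect_equal(quantile_normalize(x), x)

  # hand case: columns [1,3] and [2,4] -> both become [1.5, 3.5]
  y <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(quantile_normalize(y)), matrix(c(1.5, 3.5, 1.5, 3.5), 2))

  # random matrix: all columns share one sorted value vector afterwards
  set.seed(1)
  z <- matrix(rlnorm(1200), 200, 6)
  zn <- quantile_normalize(z)
  ref <- sort(zn[, 1])
  for (j in 2:6) expect_equal(sort(zn[, j]), ref)
  expect_equal(unname(ref), unname(rowMeans(apply(z, 2, sort))))
  expect_error(quantile_normalize(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("t-test DE matches the textbook equal-variance formula", {
  x <- matrix(c(40, 44, 38, 20, 21, 19), 1, 6,
              dimnames = list("f1", paste0("s", 1:6)))
  g <- setNames(rep(c("control", "C+T"), each = 3), colnames(x))
  de <- ttest_de(x, groups = g)
  # independent hand computation on log2(x + 1)
  a <- log2(c(40, 44, 38) + 1); b <- log2(c(20, 21, 19) + 1)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  expect_equal(de$statistic, t_hand)
  expect_equal(de$p, p_hand)
  # signed FC from linear means: 20/40.667 -> about -2
  expect_equal(de$signed_fc, -mean(c(40, 44, 38)) / mean(c(20, 21, 19)))
})

test_that("signed fold change follows the up/down ratio convention", {
  mk <- function(ctrl, trt) {
    x <- matrix(c(ctrl + c(-1, 0, 1), trt + c(-1, 0, 1)), 1, 6,
                dimnames = list("f", paste0("s", 1:6)))
    ttest_de(x, groups = setNames(rep(c("control", "T"), each = 3), colnames(x)))
  }
  expect_equal(mk(20, 40)$signed_fc, 2)
  expect_equal(mk(40, 20)$signed_fc, -2)
  # identical groups: p = 1, FC = 1, flat
  x <- matrix(rep(c(3, 4, 5), 2), 1, 6, dimnames = list("f", paste0("s", 1:6)))
  de <- ttest_de(x, groups = setNames(rep(c("control", "T"), each = 3), colnames(x)))
  expect_equal(de$p, 1)
  expect_equal(de$signed_fc, 1)
  expect_identical(de$direction, "flat")
  # < 2 samples per group is an error
  expect_error(ttest_de(x[, 1:3, drop = FALSE],
                        groups = setNames(c("a", "a", "b"), colnames(x)[1:3])),
               ">= 2 samples")
})

test_that("swapping group labels negates signed FC and preserves p", {
  set.seed(21)
  x <- matrix(rlnorm(300, 5, 1), 50, 6,
              dimnames = list(sprintf("f%02d", 1:50), paste0("s", 1:6)))
  g <- setNames(rep(c("A", "B"), each = 3), colnames(x))
  d1 <- ttest_de(x, groups = g, ref = "A")
  d2 <- ttest_de(x, groups = g, ref = "B")
  expect_equal(d1$signed_fc, -d2$signed_fc)
  expect_equal(d1$p, d2$p)
  cn <- round(x)
  n1 <- nb_exact_de(cn, groups = g, ref = "A")
  n2 <- nb_exact_de(cn, groups = g, ref = "B")
  expect_equal(n1$p, n2$p)
  expect_equal(n1$signed_fc, -n2$signed_fc)
})

test_that("BH q-values never fall below p and preserve p-ordering", {
  set.seed(3)
  x <- matrix(rlnorm(600, 6, 0.8), 100, 6,
              dimnames = list(sprintf("f%03d", 1:100), paste0("s", 1:6)))
  de <- ttest_de(x, groups = setNames(rep(c("A", "B"), each = 3), colnames(x)))
  expect_true(all(de$q >= de$p))
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-12))
})

test_that("NB exact p reduces to the exact binomial tail in the Poisson limit", {
  # sums (10 | 0), equal library sizes, dispersion -> 0
  expect_equal(nb_exact_pvalue(10, 0, 3, 3, 1e-10),
               binom.test(10, 10, 0.5)$p.value, tolerance = 1e-6)
  # independent enumeration of the minimum-likelihood two-sided tail
  for (s1 in c(7, 9)) {
    s2 <- 12 - s1
    pr <- dbinom(0:12, 12, 0.5)
    p_hand <- sum(pr[pr <= pr[s1 + 1] * (1 + 1e-7)])
    expect_equal(nb_exact_pvalue(s1, s2, 3, 3, 1e-10), p_hand, tolerance = 1e-6)
  }
  # identical counts in every sample -> p = 1
  x <- matrix(5L, 4, 6, dimnames = list(paste0("m", 1:4), paste0("s", 1:6)))
  de <- nb_exact_de(x, groups = setNames(rep(c("A", "B"), each = 3), colnames(x)))
  expect_true(all(de$p == 1))
  # all-zero feature -> p = 1, flat
  x[1, ] <- 0L; x[2, 4:6] <- 9L
  de <- nb_exact_de(x, groups = setNames(rep(c("A", "B"), each = 3), colnames(x)))
  expect_equal(de$p[1], 1)
  expect_identical(de$direction[1], "flat")
})

test_that("NB exact test agrees with edgeR's exact test on strong signals", {
  # cross-check against the independent reference implementation: the two
  # tests share the NB model but differ in dispersion estimation, so exact
  # agreement is not expected -- significance calls on clear signals are
  cfg <- sim_config(n_coding = 10, n_lnc = 10, n_mirna = 200, seed = 31)
  cnt <- gen_mirna_counts(cfg, gen_annotation(cfg)$truth)
  g <- sample_groups(cnt)
  de <- nb_exact_de(cnt)
  y <- edgeR::DGEList(counts = cnt, group = factor(g, levels = c("control", "C+T")))
  y <- edgeR::calcNormFactors(y, method = "none")
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y)$table
  strong <- abs(log2(abs(de$signed_fc))) >= 2 | et$PValue < 1e-4 | de$p < 1e-4
  agree <- (de$p[strong] <= 0.05) == (et$PValue[strong] <= 0.05)
  expect_gt(mean(agree), 0.9)
  # fold-change direction always agrees
  expect_true(all(sign(log2(abs(de$signed_fc)) * sign(de$signed_fc)) ==
                    sign(et$logFC) | et$logFC == 0))
})

test_that("apply_de_filter respects thresholds and boundaries", {
  rec <- structure(data.frame(
    feature_id = c("a", "b", "c", "d"),
    mean_ctrl = 1, mean_trt = 1,
    signed_fc = c(1.631, -3.855, 1.0, 2.0),
    statistic = 0, p = c(0.037, 0.029, 0.001, 0.06), q = 1,
    raw_intensity = 100, direction = "x", stringsAsFactors = FALSE),
    class = c("de_table", "data.frame"))
  out <- apply_de_filter(rec, de_filter())
  expect_identical(out$up, "a")     # +1.631, p 0.037
  expect_identical(out$down, "b")   # -3.855, p 0.029
  # |FC| = 1.0 and p = 0.06 both fail the gates
  expect_false("c" %in% c(out$up, out$down))
  expect_false("d" %in% c(out$up, out$down))
  expect_length(intersect(out$up, out$down), 0)
})

test_that("hierarchical clustering merges duplicates first and is label-invariant", {
  x <- matrix(c(0, 0, 5, 5, 0.01, 0.02), 3, 2, byrow = TRUE,
              dimnames = list(c("r1", "r2", "r3"), NULL))
  x[2, ] <- x[1, ]  # rows 1 and 2 identical
  hc <- hierarchical_cluster(x)
  expect_equal(hc$height[1], 0)
  expect_setequal(-hc$merge[1, ], c(1, 2))

  # 1-D points 0, 1, 10, 11: the two tight pairs merge before the final join
  y <- matrix(c(0, 1, 10, 11), 4, 1, dimnames = list(paste0("p", 1:4), NULL))
  hc2 <- hierarchical_cluster(y)
  first_two <- rbind(sort(-hc2$merge[1, ]), sort(-hc2$merge[2, ]))
  expect_true(any(first_two[, 1] == 1 & first_two[, 2] == 2))
  expect_true(any(first_two[, 1] == 3 & first_two[, 2] == 4))

  # permuting row order permutes labels but not the tree topology
  set.seed(41)
  z <- matrix(rnorm(40), 10, 4, dimnames = list(sprintf("g%02d", 1:10), NULL))
  perm <- sample(10)
  hc_a <- hierarchical_cluster(z)
  hc_b <- hierarchical_cluster(z[perm, ])
  expect_equal(sort(hc_a$height), sort(hc_b$height))
  co_a <- cophenetic(hc_a); co_b <- cophenetic(hc_b)
  m_a <- as.matrix(co_a); m_b <- as.matrix(co_b)[rownames(m_a), colnames(m_a)]
  expect_equal(m_a, m_b)
  expect_error(hierarchical_cluster(matrix(c(1, NA), 2, 1)), "non-finite")
})
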