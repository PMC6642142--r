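# Normalization and two-group differential expression.
#
# Intensities are tested with an equal-variance Student t on
# log2(x + 1); miRNA read counts with a common-dispersion negative-binomial
# exact conditional test on the two group sums. Both report a signed fold
# change on linear group means (ratio if up, -1/ratio if down, so
# |signed_fc| >= 1 always), a raw p, a BH-adjusted q, and the raw intensity
# (max of the two linear group means) used later by the sponge gate.

#' Differential-expression filter thresholds
#'
#' @param fc_min Minimum absolute signed fold change (default 1.5).
#' @param p_max Maximum p-value (default 0.05).
#' @param use_adjusted Filter on the BH-adjusted q instead of the raw p.
#'   Default `FALSE`: the raw-p cut is the conventional array screen, with q
#'   still reported alongside.
#' @return List of class `de_filter`.
#' @export
de_filter <- function(fc_min = 1.5, p_max = 0.05, use_adjusted = FALSE) {
  stopifnot(fc_min >= 1, p_max > 0, p_max <= 1, is.logical(use_adjusted))
  structure(list(fc_min = fc_min, p_max = p_max, use_adjusted = use_adjusted),
            class = "de_filter")
}

#' Quantile-normalize an intensity matrix
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' mean across samples of the sorted columns, assigned back by rank with
#' ties averaged. Row and column order are preserved. Columns that are
#' already identically distributed are a fixed point.
#'
#' @param x Numeric matrix, no missing values.
#' @return Matrix of the same shape, each column having an identical sorted
#'   value vector.
#' @export
quantile_normalize <- function(x) {
  if (!is.matrix(x) || !length(x)) stop("x must be a non-empty numeric matrix")
  if (any(is.na(x))) stop("x must not contain missing values")
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  attr(out, "groups") <- attr(x, "groups")
  out
}

.two_groups <- function(m, groups, ref) {
  if (is.null(groups)) groups <- attr(m, "groups")
  if (is.null(groups)) stop("no group labels: pass `groups` or a matrix with a groups attribute")
  groups <- as.character(groups[colnames(m)])
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two groups required, got: ", paste(lev, collapse = ", "))
  if (is.null(ref)) ref <- if ("control" %in% lev) "control" else lev[1L]
  if (!ref %in% lev) stop("reference group '", ref, "' not present")
  ctrl <- groups == ref
  if (sum(ctrl) < 2L || sum(!ctrl) < 2L) stop("each group needs >= 2 samples")
  list(ctrl = ctrl, trt = !ctrl, ref = ref, trt_label = setdiff(lev, ref))
}

.signed_fc <- function(mean_ctrl, mean_trt) {
  ratio <- ifelse(mean_ctrl == 0 & mean_trt == 0, 1,
                  ifelse(mean_ctrl == 0 | mean_trt == 0,
                         (mean_trt + 0.5) / (mean_ctrl + 0.5),
                         mean_trt / mean_ctrl))
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

.direction <- function(signed_fc, p, filter) {
  ifelse(abs(signed_fc) >= filter$fc_min & p <= filter$p_max,
         ifelse(signed_fc > 0, "up", "down"), "flat")
}

.de_table <- function(feature_id, mean_ctrl, mean_trt, statistic, p, filter,
                      method, ref) {
  p[is.na(p)] <- 1
  signed_fc <- .signed_fc(mean_ctrl, mean_trt)
  q <- stats::p.adjust(p, method = "BH")
  pp <- if (isTRUE(filter$use_adjusted)) q else p
  out <- data.frame(feature_id = feature_id, mean_ctrl = mean_ctrl,
                    mean_trt = mean_trt, signed_fc = signed_fc,
                    statistic = statistic, p = p, q = q,
                    raw_intensity = pmax(mean_ctrl, mean_trt),
                    direction = .direction(signed_fc, pp, filter),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("de_table", "data.frame"),
            method = method, reference = ref, filter = filter,
            scale = if (method == "ttest") "log2(x + 1)" else "counts")
}

#' Student's t differential expression for intensity matrices
#'
#' Per feature, an equal-variance two-sample t-test on `log2(x + 1)`
#' (pseudocount 1 for zero safety); the signed fold change is computed on the
#' linear group means. Features that are constant and equal across both
#' groups get p = 1. BH adjustment is applied across all tested features.
#'
#' @param x Linear-scale intensity matrix (features x samples), typically
#'   quantile-normalized.
#' @param groups Group labels per sample (named or in column order); may be
#'   omitted when `x` carries a `"groups"` attribute.
#' @param filter A [de_filter()] used to assign the `direction` column.
#' @param ref Reference (control) group label; defaults to `"control"` if
#'   present, else the first label.
#' @return A `de_table` data frame: `feature_id`, linear `mean_ctrl` /
#'   `mean_trt`, `signed_fc`, `statistic`, `p`, `q`, `raw_intensity`,
#'   `direction` (`up`/`down`/`flat`).
#' @export
ttest_de <- function(x, groups = NULL, filter = de_filter(), ref = NULL) {
  g <- .two_groups(x, groups, ref)
  lx <- log2(x + 1)
  a <- lx[, g$ctrl, drop = FALSE]; b <- lx[, g$trt, drop = FALSE]
  res <- vapply(seq_len(nrow(x)), function(i) {
    tt <- tryCatch(stats::t.test(b[i, ], a[i, ], var.equal = TRUE),
                   error = function(e) NULL)  # constant data -> null result
    if (is.null(tt)) c(0, 1) else c(unname(tt$statistic), tt$p.value)
  }, numeric(2))
  .de_table(rownames(x),
            mean_ctrl = rowMeans(x[, g$ctrl, drop = FALSE]),
            mean_trt = rowMeans(x[, g$trt, drop = FALSE]),
            statistic = res[1L, ], p = res[2L, ], filter = filter,
            method = "ttest", ref = g$ref)
}

#' Negative-binomial exact test for count matrices
#'
#' A simplified small-RNA count test: library sizes are scaled to a common
#' depth, a single common dispersion is estimated across features by the
#' method of moments on within-group means and variances
#' (`var = mu + phi * mu^2`, floored at 1e-8), and each feature is tested by
#' an exact conditional test on its two (depth-normalized, rounded) group
#' sums: conditional on the total, the probability of every split is
#' computed under the NB sum distribution and the two-sided p is the summed
#' probability of all splits no more likely than the observed one. As
#' `phi -> 0` this reduces to the exact conditional binomial (Poisson) test.
#' All-zero features get p = 1.
#'
#' @param x Count matrix (features x samples), non-negative integers.
#' @inheritParams ttest_de
#' @return A `de_table`; `statistic` is the normalized treated-group sum.
#' @export
nb_exact_de <- function(x, groups = NULL, filter = de_filter(), ref = NULL) {
  g <- .two_groups(x, groups, ref)
  lib <- colSums(x)
  if (any(lib <= 0)) stop("library sizes must be > 0")
  xn <- sweep(x, 2L, mean(lib) / lib, `*`)      # common-depth normalization
  n1 <- sum(g$ctrl); n2 <- sum(g$trt)
  m1 <- rowMeans(xn[, g$ctrl, drop = FALSE]); m2 <- rowMeans(xn[, g$trt, drop = FALSE])
  v1 <- apply(xn[, g$ctrl, drop = FALSE], 1L, stats::var)
  v2 <- apply(xn[, g$trt, drop = FALSE], 1L, stats::var)
  # pooled within-group moments -> per-feature phi, averaged across features
  vpool <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mpool <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ok <- mpool > 0
  phi_f <- (vpool[ok] - mpool[ok]) / mpool[ok]^2
  phi <- max(mean(phi_f), 1e-8)

  s1 <- round(rowSums(xn[, g$ctrl, drop = FALSE]))
  s2 <- round(rowSums(xn[, g$trt, drop = FALSE]))
  p <- vapply(seq_len(nrow(x)), function(i) {
    nb_exact_pvalue(s1[i], s2[i], n1, n2, phi)
  }, 0)
  .de_table(rownames(x), mean_ctrl = m1, mean_trt = m2,
            statistic = s2, p = p, filter = filter,
            method = "nb_exact", ref = g$ref)
}

#' Exact conditional negative-binomial p-value for two group sums
#'
#' Two-sided p for the split of a total count between two groups under a
#' common-mean NB model. The sum of n iid NB(mu, phi) variables is
#' NB(n * mu, phi / n) (size n / phi); conditioning on the total
#' `s = s1 + s2` removes most of the dependence on mu, whose plug-in
#' estimate is the grand mean. Two-sided convention: the summed probability
#' of every split at most as likely as the observed one (with a 1 + 1e-7
#' tolerance for ties), which reduces to the classic exact binomial test of
#' an even split in the Poisson limit `phi -> 0`.
#'
#' @param s1,s2 Group sums (non-negative integers, already depth-normalized).
#' @param n1,n2 Samples per group.
#' @param phi Common NB dispersion (> 0).
#' @return Two-sided p-value.
#' @export
nb_exact_pvalue <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  mu <- s / (n1 + n2)
  a <- 0:s
  logp <- stats::dnbinom(a, size = n1 / phi, mu = n1 * mu, log = TRUE) +
    stats::dnbinom(s - a, size = n2 / phi, mu = n2 * mu, log = TRUE)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[s1 + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Split a DE table into significant up and down id sets
#'
#' @param records A `de_table`.
#' @param filter A [de_filter()]; the raw p is gated unless
#'   `use_adjusted = TRUE`.
#' @return `list(up = ..., down = ...)` of feature ids; always disjoint.
#' @export
apply_de_filter <- function(records, filter = de_filter()) {
  stopifnot(inherits(records, "de_table"), inherits(filter, "de_filter"))
  p <- if (isTRUE(filter$use_adjusted)) records$q else records$p
  sig <- abs(records$signed_fc) >= filter$fc_min & p <= filter$p_max
  list(up = records$feature_id[sig & records$signed_fc > 0],
       down = records$feature_id[sig & records$signed_fc < 0])
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with Euclidean distance and Ward's linkage
#' (`stats::hclust`, method `"ward.D2"`), the standard display for
#' small-RNA expression patterns. Duplicated rows merge first at height 0.
#'
#' @param x Numeric matrix; rows are clustered.
#' @param distance Distance metric passed to [stats::dist()].
#' @param linkage Linkage method passed to [stats::hclust()]; `"ward"` is
#'   mapped to `"ward.D2"` (Ward on squared Euclidean increments).
#' @return An object of class `hclust` (merge tree, heights, leaf order).
#' @export
hierarchical_cluster <- function(x, distance = "euclidean", linkage = "ward") {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 rows to cluster")
  if (any(!is.finite(x))) stop("non-finite values in x")
  if (linkage == "ward") linkage <- "ward.D2"
  stats::hclust(stats::dist(x, method = distance), method = linkage)
}

#' @export
print.de_table <- function(x, ...) {
  filt <- attr(x, "filter")
  cat("Differential expression (", attr(x, "method"), "), ",
      nrow(x), " features; reference group: ", attr(x, "reference"), "\n", sep = "")
  cat("filter: |FC| >= ", filt$fc_min, ", ",
      if (isTRUE(filt$use_adjusted)) "q" else "p", " <= ", filt$p_max, "\n", sep = "")
  tab <- table(factor(x$direction, levels = c("up", "down", "flat")))
  cat("up: ", tab[["up"]], "  down: ", tab[["down"]], "  flat: ", tab[["flat"]], "\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary de_table
summary.de_table <- function(object, n = 10L, ...) {
  print(object)
  sig <- object[object$direction != "flat", , drop = FALSE]
  sig <- sig[order(sig$p), , drop = FALSE]
  cat("\ntop significant features:\n")
  print.data.frame(utils::head(sig, n), row.names = FALSE, digits = 4)
  invisible(object)
}

#' Write a DE table as TSV
#' @param records A `de_table`.
#' @param path Output path.
#' @export
write_de_tsv <- function(records, path) {
  stopifnot(inherits(records, "de_table"))
  .write_tsv(as.data.frame(records), path)
}
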