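# Group-comparison statistics for control-normalized validation
# measurements (qRT-PCR style): Kruskal-Wallis omnibus across treatment
# groups, Dunn's rank-based pairwise post hoc with BH adjustment, and
# control-relative fold presentation.

.check_groups <- function(groups, min_groups = 2L) {
  if (!is.list(groups) || length(groups) < min_groups || is.null(names(groups))) {
    stop("groups must be a named list of >= ", min_groups, " numeric vectors")
  }
  if (any(!vapply(groups, length, 0L))) {
    stop("empty group(s): ",
         paste(names(groups)[!vapply(groups, length, 0L)], collapse = ", "))
  }
  lapply(groups, as.numeric)
}

#' Kruskal-Wallis omnibus test across treatment groups
#'
#' Rank-based one-factor test of whether any group differs; H is computed
#' on midranks with the standard tie correction and referred to a
#' chi-square with (g - 1) degrees of freedom. Completely tied data (all
#' observations equal) gives H = 0, p = 1.
#'
#' @param groups Named list of numeric vectors, one per group.
#' @return `list(H, df, p)`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- .check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 0L)))
  if (length(x) < 3L) stop("need >= 3 observations in total")
  if (length(unique(x)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's rank-based pairwise post hoc test
#'
#' After a Kruskal-Wallis omnibus, compares group pairs on the midranks of
#' the pooled sample: `z = (Rbar_a - Rbar_b) / sqrt(V)` with
#' `V = (N(N+1)/12 - T) * (1/n_a + 1/n_b)` and tie correction
#' `T = sum(t^3 - t) / (12 (N - 1))`; two-sided p from the standard normal.
#' BH adjustment is computed across the requested comparisons only.
#'
#' @param groups Named list of numeric vectors.
#' @param comparisons List of length-2 character vectors of group labels;
#'   default all pairs.
#' @param adjust Multiple-testing method (default `"BH"`).
#' @return Data frame `group1`, `group2`, `z`, `p`, `q`.
#' @export
dunn_posthoc <- function(groups, comparisons = NULL, adjust = "BH") {
  groups <- .check_groups(groups)
  labs <- names(groups)
  if (is.null(comparisons)) {
    comparisons <- utils::combn(labs, 2L, simplify = FALSE)
  }
  bad <- unlist(comparisons)[!unlist(comparisons) %in% labs]
  if (length(bad)) stop("unknown group label(s): ", paste(unique(bad), collapse = ", "))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(labs, vapply(groups, length, 0L))
  N <- length(x)
  r <- rank(x)                               # midranks
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_corr
  res <- lapply(comparisons, function(cp) {
    a <- cp[1L]; b <- cp[2L]
    v <- v0 * (1 / n[[a]] + 1 / n[[b]])
    z <- if (v <= 0) 0 else (rbar[[a]] - rbar[[b]]) / sqrt(v)
    data.frame(group1 = a, group2 = b, z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  out
}

#' Per-group fold change relative to a reference group
#'
#' `fold(g) = mean(g) / mean(reference)`; the reference row is exactly 1 by
#' construction (it is the normalization anchor, which is why bar plots of
#' such data show no error bar on the control).
#'
#' @param groups Named list of numeric vectors.
#' @param reference Reference group label (default `"control"` if present,
#'   else the first group).
#' @return Data frame `group`, `mean`, `fold`.
#' @export
relative_fold <- function(groups, reference = NULL) {
  groups <- .check_groups(groups, min_groups = 1L)
  if (is.null(reference)) {
    reference <- if ("control" %in% names(groups)) "control" else names(groups)[1L]
  }
  if (!reference %in% names(groups)) stop("reference group '", reference, "' not present")
  means <- vapply(groups, mean, 0)
  if (means[[reference]] == 0) stop("reference group mean is zero")
  fold <- means / means[[reference]]
  fold[reference] <- 1
  data.frame(group = names(groups), mean = unname(means), fold = unname(fold),
             stringsAsFactors = FALSE)
}
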