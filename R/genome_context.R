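# Genomic-context classification of lncRNAs and cis candidate pairing.
#
# All coordinates are 0-based half-open (see read_gtf), so the gap between
# two intervals on the same chromosome is max(0, max(start) - min(end)) and
# intervals overlap iff start1 < end2 && start2 < end1.

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

.gap <- function(s1, e1, s2, e2) pmax(0, pmax(s1, s2) - pmin(e1, e2))

.genes_of <- function(features, biotype = NULL) {
  g <- features[features$type == "gene", , drop = FALSE]
  if (!is.null(biotype)) g <- g[g$biotype == biotype, , drop = FALSE]
  g
}

# Exonic intervals per coding gene; genes without exon records count their
# whole span as exonic (single-exon fallback, which makes the
# intronic-antisense class unreachable for them).
.exonic_intervals <- function(features) {
  genes <- .genes_of(features, "coding")
  exons <- features[features$type == "exon" & features$gene_id %in% genes$id, ,
                    drop = FALSE]
  no_exon <- setdiff(genes$id, exons$gene_id)
  if (length(no_exon)) {
    add <- genes[genes$id %in% no_exon, , drop = FALSE]
    add$type <- "exon"
    exons <- rbind(exons, add)
  }
  exons
}

#' Classify one lncRNA by its position relative to coding genes
#'
#' Classes are assigned by a fixed priority order: overlap with a coding
#' exon on the opposite strand is `natural_antisense`; full containment in
#' a coding intron on the opposite strand is `intronic_antisense`; any
#' same-strand overlap with a coding gene is `sense_overlap`; a head-to-head
#' arrangement with transcription start sites within 1 kb and no overlap is
#' `bidirectional`; everything else is `intergenic`. The priority order
#' makes the labels exhaustive and mutually exclusive.
#'
#' @param lnc_id Id of a lncRNA gene present in `features`.
#' @param features Annotation data frame in the [read_gtf()] layout.
#' @return One of `"intergenic"`, `"natural_antisense"`,
#'   `"intronic_antisense"`, `"sense_overlap"`, `"bidirectional"`.
#' @export
classify_lncrna <- function(lnc_id, features) {
  lnc <- features[features$id == lnc_id & features$type == "gene", , drop = FALSE]
  if (nrow(lnc) != 1L) stop("unknown feature id: ", lnc_id)
  if (lnc$biotype != "lncRNA") stop("feature ", lnc_id, " is not a lncRNA")
  genes <- .genes_of(features, "coding")
  exons <- .exonic_intervals(features)
  same_chr <- genes$chrom == lnc$chrom
  opp <- genes$strand != lnc$strand & genes$strand %in% c("+", "-") &
    lnc$strand %in% c("+", "-")

  ex_same <- exons[exons$chrom == lnc$chrom, , drop = FALSE]
  ex_hit <- ex_same[.overlaps(lnc$start, lnc$end, ex_same$start, ex_same$end), ,
                    drop = FALSE]
  ex_opp <- ex_hit$gene_id[ex_hit$strand != lnc$strand]
  if (length(ex_opp)) return("natural_antisense")

  ov <- same_chr & .overlaps(lnc$start, lnc$end, genes$start, genes$end)
  # fully inside the gene body, opposite strand, touching no exon -> intronic
  inside <- ov & opp & genes$start <= lnc$start & lnc$end <= genes$end
  if (any(inside)) {
    cand <- genes$id[inside]
    touches_exon <- vapply(cand, function(gid) {
      e <- exons[exons$gene_id == gid, , drop = FALSE]
      any(.overlaps(lnc$start, lnc$end, e$start, e$end))
    }, TRUE)
    if (any(!touches_exon)) return("intronic_antisense")
  }
  if (any(ov & genes$strand == lnc$strand)) return("sense_overlap")

  # head-to-head promoters within 1 kb, divergent transcription, no overlap
  if (lnc$strand %in% c("+", "-")) {
    cand <- genes[same_chr & opp & !ov, , drop = FALSE]
    if (nrow(cand)) {
      h2h <- (lnc$strand == "-" & cand$strand == "+" &
                lnc$end <= cand$start & cand$start - lnc$end <= 1000) |
             (lnc$strand == "+" & cand$strand == "-" &
                cand$end <= lnc$start & lnc$start - cand$end <= 1000)
      if (any(h2h)) return("bidirectional")
    }
  }
  "intergenic"
}

#' Classify every lncRNA in an annotation
#'
#' @param features Annotation data frame ([read_gtf()] layout).
#' @return Named character vector, one class per lncRNA gene.
#' @export
classify_lncrnas <- function(features) {
  lnc_ids <- .genes_of(features, "lncRNA")$id
  stats::setNames(vapply(lnc_ids, classify_lncrna, "", features = features), lnc_ids)
}

.pair_df <- function(lnc_id = character(), mrna_id = character(),
                     distance_bp = numeric(), relation = character()) {
  data.frame(lnc_id = lnc_id, mrna_id = mrna_id, distance_bp = distance_bp,
             relation = relation, stringsAsFactors = FALSE)
}

#' Proximity pairs between lncRNAs and coding genes
#'
#' Emits a pair for every lncRNA/coding-gene combination on the same
#' chromosome whose interval gap (distance between the closest interval
#' ends; 0 if they overlap) is strictly below `window`. Strand is ignored:
#' cis regulation does not require a particular orientation.
#'
#' @param lnc_set,mrna_set Feature data frames (gene rows; [read_gtf()]
#'   layout) or id vectors resolved against `features`.
#' @param window Window in bp (default 300000); strict `<` at the boundary.
#' @param features Optional annotation to resolve id vectors against.
#' @return Data frame `lnc_id`, `mrna_id`, `distance_bp`,
#'   `relation = "proximal"`.
#' @export
proximity_pairs <- function(lnc_set, mrna_set, window = 300000, features = NULL) {
  stopifnot(window > 0)
  lnc <- .resolve_features(lnc_set, features, "lncRNA")
  mrna <- .resolve_features(mrna_set, features, "coding")
  if (!nrow(lnc) || !nrow(mrna)) return(.pair_df())
  out <- lapply(seq_len(nrow(lnc)), function(i) {
    same <- mrna$chrom == lnc$chrom[i]
    if (!any(same)) return(NULL)
    m <- mrna[same, , drop = FALSE]
    d <- .gap(lnc$start[i], lnc$end[i], m$start, m$end)
    keep <- d < window
    if (!any(keep)) return(NULL)
    .pair_df(rep(lnc$id[i], sum(keep)), m$id[keep], d[keep],
             rep("proximal", sum(keep)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .pair_df() else out
}

#' Antisense overlap pairs between lncRNAs and coding genes
#'
#' A pair is emitted iff the two gene intervals overlap (by at least 1 bp)
#' on opposite strands.
#'
#' @inheritParams proximity_pairs
#' @return Data frame with `distance_bp = 0` and
#'   `relation = "antisense_overlap"`.
#' @export
antisense_pairs <- function(lnc_set, mrna_set, features = NULL) {
  lnc <- .resolve_features(lnc_set, features, "lncRNA")
  mrna <- .resolve_features(mrna_set, features, "coding")
  if (!nrow(lnc) || !nrow(mrna)) return(.pair_df())
  out <- lapply(seq_len(nrow(lnc)), function(i) {
    if (!lnc$strand[i] %in% c("+", "-")) return(NULL)
    hit <- mrna$chrom == lnc$chrom[i] &
      mrna$strand != lnc$strand[i] & mrna$strand %in% c("+", "-") &
      .overlaps(lnc$start[i], lnc$end[i], mrna$start, mrna$end)
    if (!any(hit)) return(NULL)
    .pair_df(rep(lnc$id[i], sum(hit)), mrna$id[hit], rep(0, sum(hit)),
             rep("antisense_overlap", sum(hit)))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) .pair_df() else out
}

.resolve_features <- function(x, features, biotype) {
  if (is.data.frame(x)) return(x[x$type == "gene", , drop = FALSE])
  if (is.null(features)) stop("pass feature data frames, or ids plus `features`")
  g <- .genes_of(features, biotype)
  missing <- setdiff(x, g$id)
  if (length(missing)) stop("unknown ", biotype, " id(s): ", paste(missing, collapse = ", "))
  g[match(x, g$id), , drop = FALSE]
}

#' Summarize lncRNAs by class, size and chromosome
#'
#' @param features Annotation data frame.
#' @param classes Named class vector from [classify_lncrnas()]; computed if
#'   omitted.
#' @param size_breaks Bin edges (bp) for the size histogram.
#' @return List of three data frames (`by_class`, `by_size`, `by_chrom`),
#'   each with `count` and `percent` (percentages sum to 100 up to
#'   rounding).
#' @export
summarize_lncrna <- function(features, classes = NULL,
                             size_breaks = c(0, 200, 500, 1000, 5000, 10000,
                                             50000, Inf)) {
  lnc <- .genes_of(features, "lncRNA")
  if (!nrow(lnc)) stop("no lncRNA genes in annotation")
  if (is.null(classes)) classes <- classify_lncrnas(features)
  tab <- function(x) {
    t <- table(x)
    data.frame(level = names(t), count = as.integer(t),
               percent = round(100 * as.integer(t) / length(x), 1),
               stringsAsFactors = FALSE)
  }
  sizes <- cut(lnc$end - lnc$start, breaks = size_breaks, right = FALSE)
  list(by_class = tab(classes[lnc$id]),
       by_size = tab(sizes),
       by_chrom = tab(lnc$chrom))
}
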