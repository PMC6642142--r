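# -- shared format-error helper ----------------------------------------------

stop_format <- function(...) {
  stop(structure(class = c("spongenet_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

# -- expression / count matrices ---------------------------------------------

#' Read an expression matrix from a tab-separated file
#'
#' The file must have a header row of sample identifiers and a first column
#' of feature identifiers; all remaining cells are linear-scale, non-negative
#' intensities. Values are kept on the linear scale: any log transform is the
#' business of the differential-expression step, because the raw-intensity
#' gate used during sponge-lncRNA selection is defined on linear intensities.
#'
#' @param path Path to a TSV file.
#' @param group_map Optional named character vector mapping every sample id
#'   to a group label (e.g. `c(ctrl_1 = "control", trt_1 = "C+T")`). If
#'   given, a missing label for any sample is an error: the group design is
#'   load-bearing downstream, so silent drops are not allowed.
#' @return A numeric matrix (features x samples) with row/column names; when
#'   `group_map` is supplied the matrix carries a `"groups"` attribute, a
#'   named character vector in column order.
#' @seealso [write_expression_tsv()], [read_counts_tsv()]
#' @export
read_expression_tsv <- function(path, group_map = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 2L) stop_format("expression file needs >= 1 sample column: ", path)
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop_format("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  dup_s <- sample_ids[duplicated(sample_ids)]
  if (length(dup_s)) stop_format("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1L, drop = FALSE], 2L, as.numeric))) &
                   !is.na(as.matrix(df[, -1L, drop = FALSE])), arr.ind = TRUE)
    if (nrow(bad)) {
      stop_format("non-numeric cell at row ", bad[1L, 1L], " (feature ", ids[bad[1L, 1L]],
                  "), column ", sample_ids[bad[1L, 2L]])
    }
    stop_format("non-numeric values in ", path)
  }
  if (any(!is.finite(vals))) stop_format("non-finite value(s) in ", path)
  if (any(vals < 0)) stop_format("negative intensity value(s) in ", path)
  rownames(vals) <- ids
  if (!is.null(group_map)) attr(vals, "groups") <- .match_groups(sample_ids, group_map)
  vals
}

.match_groups <- function(sample_ids, group_map) {
  if (is.null(names(group_map))) stop_format("group_map must be a named vector (sample -> group)")
  missing <- setdiff(sample_ids, names(group_map))
  if (length(missing)) {
    stop_format("no group label for sample(s): ", paste(missing, collapse = ", "))
  }
  g <- group_map[sample_ids]
  stats::setNames(as.character(g), sample_ids)
}

#' Write an expression or count matrix as TSV
#'
#' Inverse of [read_expression_tsv()]; the first column is named
#' `feature_id` and row order is preserved, so read/write round-trips are
#' lossless.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output path.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(feature_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read a miRNA read-count matrix
#'
#' Same layout as [read_expression_tsv()] but values must be non-negative
#' integers and every sample must have a positive library size (column sum).
#'
#' @inheritParams read_expression_tsv
#' @return Integer-valued numeric matrix, optionally with a `"groups"`
#'   attribute.
#' @export
read_counts_tsv <- function(path, group_map = NULL) {
  m <- read_expression_tsv(path, group_map)
  if (any(m != round(m))) stop_format("non-integer count value(s) in ", path)
  if (any(colSums(m) <= 0)) {
    stop_format("zero library size for sample(s): ",
                paste(colnames(m)[colSums(m) <= 0], collapse = ", "))
  }
  m
}

#' Sample group labels attached to a matrix
#' @param x Matrix read with a `group_map`.
#' @return Named character vector of group labels in column order.
#' @export
sample_groups <- function(x) {
  g <- attr(x, "groups")
  if (is.null(g)) stop("matrix carries no group labels; pass group_map when reading")
  g
}

# -- genome annotation --------------------------------------------------------

.normalize_biotype <- function(b) {
  b <- tolower(ifelse(is.na(b), "", b))
  out <- rep("other", length(b))
  out[b %in% c("protein_coding", "coding", "mrna")] <- "coding"
  out[grepl("lincrna|lncrna|antisense|non_coding|noncoding|processed_transcript", b)] <- "lncRNA"
  out
}

#' Read gene/exon features from a GTF file
#'
#' Coordinates are converted from the GTF's 1-based inclusive convention to
#' the package's internal 0-based half-open convention (BED-like), so that
#' interval lengths are simply `end - start` and gap/overlap arithmetic
#' needs no off-by-one corrections. Biotypes are normalized to
#' `coding` / `lncRNA` / `other` from either a `gene_biotype` or a
#' `gene_type` attribute.
#'
#' @param path Path to a GTF file. Only `gene` and `exon` records are kept.
#' @return A `data.frame` with columns `id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-` or `.`), `biotype`, `type` (`gene`/`exon`) and
#'   `gene_id` (parent gene for exons).
#' @export
read_gtf <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stop_format("GTF format error in ", path, ": ",
                                                 conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  keep <- df$type %in% c("gene", "exon")
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) stop_format("no gene/exon records in ", path)
  strand <- as.character(df$strand)
  strand[strand == "*"] <- "."
  if (!all(strand %in% c("+", "-", "."))) {
    stop_format("unknown strand symbol(s): ",
                paste(unique(setdiff(strand, c("+", "-", "."))), collapse = ", "))
  }
  bio <- if ("gene_biotype" %in% names(df)) df$gene_biotype else NA_character_
  if ("gene_type" %in% names(df)) {
    alt <- df$gene_type
    bio <- ifelse(is.na(bio), alt, bio)
  }
  out <- data.frame(
    id      = ifelse(df$type == "gene", df$gene_id,
                     paste0(df$gene_id, ":exon:", seq_len(nrow(df)))),
    chrom   = as.character(df$seqnames),
    start   = df$start - 1L,          # 1-based inclusive -> 0-based half-open
    end     = df$end,
    strand  = strand,
    biotype = .normalize_biotype(bio),
    type    = as.character(df$type),
    gene_id = df$gene_id,
    stringsAsFactors = FALSE
  )
  gene_ids <- out$id[out$type == "gene"]
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop_format("duplicate gene id(s): ", paste(unique(dup), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Write features to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open coordinates are
#' shifted back to GTF's 1-based inclusive convention.
#'
#' @param features Feature data frame in the [read_gtf()] layout.
#' @param path Output path.
#' @export
write_gtf <- function(features, path) {
  bio <- c(coding = "protein_coding", lncRNA = "lncRNA", other = "misc_RNA")[features$biotype]
  lines <- sprintf('%s\tspongenet\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
                   features$chrom, features$type,
                   features$start + 1L, features$end,
                   features$strand, features$gene_id, bio)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# -- gene sets (GMT) ----------------------------------------------------------

#' Read a GMT gene-set collection
#'
#' Each line is `set_id <TAB> description <TAB> member...`. Members are
#' de-duplicated within a set and empty sets are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors; each element carries a
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) stop_format("GMT line without set id + description: line ", which(bad)[1L])
  sets <- lapply(parts, function(p) {
    members <- unique(p[-(1:2)])
    members <- members[nzchar(members)]
    structure(members, description = p[2L])
  })
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) {
    stop_format("duplicate set id(s): ",
                paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  }
  sets[lengths(sets) > 0L]
}

#' Write a gene-set collection as GMT
#' @param sets Named list of character vectors (as from [read_gmt()]).
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    desc <- attr(sets[[id]], "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# -- interaction tables -------------------------------------------------------

.interaction_kinds <- c("lnc_mirna_binding", "mirna_mrna_target",
                        "lnc_mrna_coexpression", "lnc_disease")

.attribute_col <- c(lnc_mirna_binding    = "binding_sites",
                    mirna_mrna_target    = "evidence",
                    lnc_mrna_coexpression = "r",
                    lnc_disease          = "disease")

#' Construct and validate an interaction table
#'
#' The four table kinds mirror the public resources the pipeline consumes:
#' lncRNA–miRNA binding sites (LncBase-style, attribute = positive integer
#' binding-site count), validated miRNA–mRNA targets (TarBase/miRecords-style,
#' attribute = evidence label), lncRNA–mRNA co-expression (lnCaNet-style,
#' attribute = correlation in \[-1, 1\]) and lncRNA–disease annotations
#' (attribute = disease label).
#'
#' @param source_id,target_id Character vectors of interaction endpoints.
#' @param attribute Attribute vector, domain fixed by `kind`.
#' @param kind One of `r paste(sQuote(c("lnc_mirna_binding", "mirna_mrna_target", "lnc_mrna_coexpression", "lnc_disease")), collapse = ", ")`.
#' @return A `data.frame` of class `interaction_table` with the attribute
#'   column named after its kind and a `"kind"` attribute.
#' @export
interaction_table <- function(source_id, target_id, attribute, kind) {
  kind <- match.arg(kind, .interaction_kinds)
  df <- data.frame(source_id = as.character(source_id),
                   target_id = as.character(target_id),
                   stringsAsFactors = FALSE)
  key <- paste(df$source_id, df$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_format("duplicate interaction (", d$source_id, ", ", d$target_id, ") in ", kind, " table")
  }
  col <- .attribute_col[[kind]]
  if (kind == "lnc_mirna_binding") {
    attribute <- suppressWarnings(as.numeric(attribute))
    if (any(is.na(attribute) | attribute < 1 | attribute != round(attribute))) {
      stop_format("binding_site_count must be a positive integer")
    }
    attribute <- as.integer(attribute)
  } else if (kind == "lnc_mrna_coexpression") {
    attribute <- suppressWarnings(as.numeric(attribute))
    if (any(is.na(attribute) | abs(attribute) > 1)) {
      stop_format("correlation r outside [-1, 1]")
    }
  } else {
    attribute <- as.character(attribute)
  }
  df[[col]] <- attribute
  structure(df, kind = kind, class = c("interaction_table", "data.frame"))
}

#' Read an interaction table from TSV
#'
#' @param path TSV with columns `source_id`, `target_id` and the kind's
#'   attribute column (`binding_sites`, `evidence`, `r` or `disease`).
#' @param kind Table kind; see [interaction_table()].
#' @export
read_interactions_tsv <- function(path, kind) {
  kind <- match.arg(kind, .interaction_kinds)
  df <- .read_tsv(path)
  col <- .attribute_col[[kind]]
  need <- c("source_id", "target_id", col)
  if (!all(need %in% colnames(df))) {
    stop_format("interaction table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  interaction_table(df$source_id, df$target_id, df[[col]], kind)
}

#' Write an interaction table as TSV
#' @param tab An `interaction_table`.
#' @param path Output path.
#' @export
write_interactions_tsv <- function(tab, path) {
  stopifnot(inherits(tab, "interaction_table"))
  .write_tsv(as.data.frame(tab), path)
}

#' Kind of an interaction table
#' @param tab An `interaction_table`.
#' @export
interaction_kind <- function(tab) attr(tab, "kind")
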