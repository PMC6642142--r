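# Bidirectional ceRNA ("sponge") network construction.
#
# A sponge triad is a directed hypothesis lncRNA -> miRNA -> mRNA in which
# the lncRNA and mRNA move together and the miRNA moves oppositely
# (forward: lnc up, miRNA down, mRNA up; reverse mirrored). Triads are
# assembled into a tripartite graph whose lnc-miRNA edges are weighted by
# binding-site counts. Slash-joined labels such as "MAGEA3/MAGEA6" are kept
# as single opaque node identifiers.

#' Select candidate sponge lncRNAs
#'
#' Highly expressed lncRNAs sponge more effectively, so candidates must be
#' significant in the requested direction, have raw signal intensity
#' strictly above `intensity_min`, and (when a whitelist is given) be
#' present in the annotation whitelist. These are the gates of the
#' up-regulated analysis; the down-regulated (reverse) analysis applies
#' significance only, i.e. `intensity_min = 0, whitelist = NULL`.
#'
#' @param lnc_de A `de_table` for lncRNAs.
#' @param direction `"up"` or `"down"`.
#' @param intensity_min Raw-intensity gate (strict `>`; default 100).
#' @param whitelist Optional character vector of annotated lncRNA ids.
#' @return Character vector of selected lncRNA ids.
#' @export
select_sponge_lncrnas <- function(lnc_de, direction = c("up", "down"),
                                  intensity_min = 100, whitelist = NULL) {
  stopifnot(inherits(lnc_de, "de_table"))
  direction <- match.arg(direction)
  keep <- lnc_de$direction == direction & lnc_de$raw_intensity > intensity_min
  if (!is.null(whitelist)) keep <- keep & lnc_de$feature_id %in% whitelist
  lnc_de$feature_id[keep]
}

.opposite <- c(up = "down", down = "up")

.sponge_triads <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(lnc_id = character(), mirna_id = character(),
                     mrna_id = character(), direction = character(),
                     binding_sites = integer(), lnc_fc = numeric(),
                     mirna_fc = numeric(), mrna_fc = numeric(),
                     stringsAsFactors = FALSE)
  }
  rownames(df) <- NULL
  structure(df, class = c("sponge_triads", "data.frame"))
}

#' Build DE-gated sponge triads
#'
#' A triad (L, M, G) is emitted iff L is in the selected lncRNA set, M is
#' significant in the direction opposite to `direction`, (L, M) is in the
#' binding table, G is significant in the same direction as L, and (M, G)
#' is in the target table. Every gate is a necessary condition, so
#' tightening any input (raising the intensity gate, shrinking the
#' whitelist) can only remove triads, never add one.
#'
#' @param lnc_set Selected lncRNA ids ([select_sponge_lncrnas()]).
#' @param mirna_de,mrna_de `de_table`s for miRNAs and mRNAs.
#' @param binding_table `interaction_table` of kind `lnc_mirna_binding`.
#' @param target_table `interaction_table` of kind `mirna_mrna_target`.
#' @param direction Direction of the lncRNA/mRNA legs (`"up"` = forward
#'   network, `"down"` = reverse).
#' @param lnc_de Optional lncRNA `de_table` used to annotate `lnc_fc`.
#' @param min_evidence Optional evidence label(s) required on target-table
#'   rows (default: none; target tables are pre-curated inputs).
#' @return Data frame of class `sponge_triads`: `lnc_id`, `mirna_id`,
#'   `mrna_id`, `direction` (`forward`/`reverse`), `binding_sites`,
#'   `lnc_fc`, `mirna_fc`, `mrna_fc`, sorted by (lnc, miRNA, mRNA).
#' @export
build_sponge_triads <- function(lnc_set, mirna_de, mrna_de, binding_table,
                                target_table, direction = c("up", "down"),
                                lnc_de = NULL, min_evidence = NULL) {
  direction <- match.arg(direction)
  stopifnot(inherits(mirna_de, "de_table"), inherits(mrna_de, "de_table"))
  if (interaction_kind(binding_table) != "lnc_mirna_binding") {
    stop("binding_table must have kind lnc_mirna_binding")
  }
  if (interaction_kind(target_table) != "mirna_mrna_target") {
    stop("target_table must have kind mirna_mrna_target")
  }
  mir_ids <- mirna_de$feature_id[mirna_de$direction == .opposite[[direction]]]
  mrna_ids <- mrna_de$feature_id[mrna_de$direction == direction]
  bind <- as.data.frame(binding_table)
  bind <- bind[bind$source_id %in% lnc_set & bind$target_id %in% mir_ids, ,
               drop = FALSE]
  targ <- as.data.frame(target_table)
  if (!is.null(min_evidence)) targ <- targ[targ$evidence %in% min_evidence, , drop = FALSE]
  targ <- targ[targ$target_id %in% mrna_ids, , drop = FALSE]
  out <- merge(bind, targ, by.x = "target_id", by.y = "source_id",
               suffixes = c("", ".t"))
  if (!nrow(out)) return(.sponge_triads())
  fc_of <- function(de, ids) de$signed_fc[match(ids, de$feature_id)]
  tri <- data.frame(
    lnc_id = out$source_id, mirna_id = out$target_id, mrna_id = out$target_id.t,
    direction = if (direction == "up") "forward" else "reverse",
    binding_sites = out$binding_sites,
    lnc_fc = if (is.null(lnc_de)) NA_real_ else fc_of(lnc_de, out$source_id),
    mirna_fc = fc_of(mirna_de, out$target_id),
    mrna_fc = fc_of(mrna_de, out$target_id.t),
    stringsAsFactors = FALSE)
  tri <- tri[order(tri$lnc_id, tri$mirna_id, tri$mrna_id), , drop = FALSE]
  .sponge_triads(tri)
}

#' Expand a printed sponge-pair table into triads
#'
#' Takes an already-filtered lncRNA–miRNA table (columns `lncrna_id`,
#' `lnc_fc`, `lnc_p`, `mirna_id`, `binding_sites`, `mirna_fc`, `mirna_p`,
#' as published network tables print them) and a miRNA–mRNA target table,
#' and expands every (lncRNA, miRNA) row against the miRNA's targets. No DE
#' gates are re-applied: such tables are the *output* of the gating, so
#' their rows are taken at face value.
#'
#' @param sponge_pairs Data frame in the printed-table layout above.
#' @param target_table `interaction_table` of kind `mirna_mrna_target`, or a
#'   data frame with columns `mirna_id`, `mrna_id`.
#' @param direction `"forward"` or `"reverse"`.
#' @return A `sponge_triads` data frame.
#' @export
triads_from_pair_table <- function(sponge_pairs, target_table,
                                   direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  need <- c("lncrna_id", "lnc_fc", "mirna_id", "binding_sites", "mirna_fc")
  if (!all(need %in% colnames(sponge_pairs))) {
    stop("sponge_pairs must have columns: ", paste(need, collapse = ", "))
  }
  if (inherits(target_table, "interaction_table")) {
    stopifnot(interaction_kind(target_table) == "mirna_mrna_target")
    targ <- data.frame(mirna_id = target_table$source_id,
                       mrna_id = target_table$target_id, stringsAsFactors = FALSE)
  } else {
    targ <- target_table[, c("mirna_id", "mrna_id")]
  }
  out <- merge(sponge_pairs, targ, by = "mirna_id")
  tri <- data.frame(lnc_id = out$lncrna_id, mirna_id = out$mirna_id,
                    mrna_id = out$mrna_id, direction = direction,
                    binding_sites = as.integer(out$binding_sites),
                    lnc_fc = out$lnc_fc, mirna_fc = out$mirna_fc,
                    mrna_fc = NA_real_, stringsAsFactors = FALSE)
  tri <- tri[order(tri$lnc_id, tri$mirna_id, tri$mrna_id), , drop = FALSE]
  .sponge_triads(tri)
}

#' Load a packaged published sponge-network fixture
#'
#' The package ships the two fully printed sponge-network tables of the
#' cocaine + Tat smooth-muscle study as plain-text fixtures: the forward
#' network (up-regulated lncRNAs/mRNAs with down-regulated miRNAs) and the
#' reverse network (down-regulated lncRNAs/mRNAs with up-regulated miRNAs).
#'
#' @param which `"forward"` or `"reverse"`.
#' @return `list(pairs, targets, triads)`: the lncRNA–miRNA pair table, the
#'   miRNA–mRNA target table and the expanded `sponge_triads`.
#' @export
sponge_fixture <- function(which = c("forward", "reverse")) {
  which <- match.arg(which)
  pairs <- .read_tsv(system.file("extdata", paste0(which, "_sponge_pairs.tsv"),
                                 package = "spongenet", mustWork = TRUE))
  targets <- .read_tsv(system.file("extdata", paste0(which, "_mirna_targets.tsv"),
                                   package = "spongenet", mustWork = TRUE))
  list(pairs = pairs, targets = targets,
       triads = triads_from_pair_table(pairs, targets, direction = which))
}

#' Assemble sponge triads into a tripartite ceRNA network
#'
#' Nodes are typed `lncRNA` / `miRNA` / `mRNA`; edges are typed `lnc_mirna`
#' (weighted by binding sites) or `mirna_mrna`. Forward triads must have
#' lnc up / miRNA down / mRNA up fold changes where fold changes are known
#' (reverse mirrored); an inconsistent triad is an error. Every node is
#' incident to at least one edge by construction.
#'
#' @param triads_forward,triads_reverse `sponge_triads` (either may be
#'   `NULL`).
#' @return Object of class `cerna_network`: `list(nodes, edges)` data
#'   frames.
#' @export
assemble_network <- function(triads_forward = NULL, triads_reverse = NULL) {
  tris <- rbind(if (!is.null(triads_forward)) as.data.frame(triads_forward),
                if (!is.null(triads_reverse)) as.data.frame(triads_reverse))
  if (is.null(tris) || !nrow(tris)) stop("no triads to assemble")
  .check_triad_consistency(tris)

  node <- function(id, class, fc) {
    data.frame(id = id, class = class, signed_fc = fc, stringsAsFactors = FALSE)
  }
  nodes <- rbind(node(tris$lnc_id, "lncRNA", tris$lnc_fc),
                 node(tris$mirna_id, "miRNA", tris$mirna_fc),
                 node(tris$mrna_id, "mRNA", tris$mrna_fc))
  nodes <- nodes[!duplicated(nodes$id), , drop = FALSE]
  nodes <- nodes[order(nodes$class, nodes$id), , drop = FALSE]

  e1 <- data.frame(source = tris$lnc_id, target = tris$mirna_id,
                   edge_type = "lnc_mirna", attribute = tris$binding_sites,
                   stringsAsFactors = FALSE)
  e2 <- data.frame(source = tris$mirna_id, target = tris$mrna_id,
                   edge_type = "mirna_mrna", attribute = NA_integer_,
                   stringsAsFactors = FALSE)
  edges <- rbind(e1, e2)
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$edge_type)), ,
                 drop = FALSE]
  edges <- edges[order(edges$edge_type, edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, triads = .sponge_triads(tris)),
            class = "cerna_network")
}

.check_triad_consistency <- function(tris) {
  sgn <- function(x) ifelse(is.na(x), NA, sign(x))
  fwd <- tris$direction == "forward"
  bad <- (fwd & (sgn(tris$lnc_fc) < 0 | sgn(tris$mirna_fc) > 0 | sgn(tris$mrna_fc) < 0)) |
    (!fwd & (sgn(tris$lnc_fc) > 0 | sgn(tris$mirna_fc) < 0 | sgn(tris$mrna_fc) > 0))
  bad[is.na(bad)] <- FALSE
  if (any(bad)) {
    stop("direction-inconsistent triad(s), e.g. (",
         paste(unlist(tris[which(bad)[1L], c("lnc_id", "mirna_id", "mrna_id")]),
               collapse = ", "), ")")
  }
  if (any(!is.na(tris$binding_sites) & tris$binding_sites < 1)) {
    stop("binding_sites must be >= 1")
  }
}

#' Per-node statistics of a ceRNA network
#'
#' @param network A `cerna_network`.
#' @return Data frame `id`, `class`, `degree`, `total_binding_sites` (lncRNA
#'   nodes: summed binding sites over their miRNA partners) and
#'   `distinct_targets` (miRNA nodes: number of distinct mRNA partners).
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  nodes <- network$nodes; edges <- network$edges
  deg <- table(c(edges$source, edges$target))
  bs <- tapply(edges$attribute[edges$edge_type == "lnc_mirna"],
               edges$source[edges$edge_type == "lnc_mirna"], sum)
  nt <- tapply(edges$target[edges$edge_type == "mirna_mrna"],
               edges$source[edges$edge_type == "mirna_mrna"],
               function(x) length(unique(x)))
  data.frame(id = nodes$id, class = nodes$class,
             degree = as.integer(deg[nodes$id]),
             total_binding_sites = ifelse(nodes$class == "lncRNA",
                                          as.integer(bs[nodes$id]), NA_integer_),
             distinct_targets = ifelse(nodes$class == "miRNA",
                                       as.integer(nt[nodes$id]), NA_integer_),
             stringsAsFactors = FALSE)
}

#' Write a ceRNA network as node and edge TSV tables
#'
#' @param network A `cerna_network`.
#' @param node_path,edge_path Output paths.
#' @export
write_network <- function(network, node_path, edge_path) {
  stopifnot(inherits(network, "cerna_network"))
  .write_tsv(network$nodes, node_path)
  .write_tsv(network$edges, edge_path)
  invisible(c(node_path, edge_path))
}

#' Convert a ceRNA network to an igraph graph
#' @param network A `cerna_network`.
#' @return A directed `igraph` graph with node `class` and edge
#'   `edge_type`/`weight` attributes.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cerna_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                     vertices = network$nodes)
  igraph::E(g)$weight <- ifelse(is.na(network$edges$attribute), 1,
                                network$edges$attribute)
  g
}

#' @export
print.cerna_network <- function(x, ...) {
  n <- table(factor(x$nodes$class, levels = c("lncRNA", "miRNA", "mRNA")))
  e <- table(factor(x$edges$edge_type, levels = c("lnc_mirna", "mirna_mrna")))
  cat("ceRNA sponge network\n")
  cat("nodes: ", n[["lncRNA"]], " lncRNA, ", n[["miRNA"]], " miRNA, ",
      n[["mRNA"]], " mRNA\n", sep = "")
  cat("edges: ", e[["lnc_mirna"]], " lncRNA-miRNA, ", e[["mirna_mrna"]],
      " miRNA-mRNA\n", sep = "")
  invisible(x)
}

#' @export
#' @method summary cerna_network
summary.cerna_network <- function(object, ...) {
  print(object)
  st <- network_stats(object)
  lnc <- st[st$class == "lncRNA", , drop = FALSE]
  lnc <- lnc[order(-lnc$total_binding_sites), , drop = FALSE]
  cat("\nlncRNA hubs (by total binding sites):\n")
  print.data.frame(utils::head(lnc[, c("id", "degree", "total_binding_sites")], 10),
                   row.names = FALSE)
  invisible(object)
}

#' @export
#' @method plot cerna_network
plot.cerna_network <- function(x, vertex_cex = 1, ...) {
  g <- as_igraph(x)
  cols <- c(lncRNA = "#D55E00", miRNA = "#0072B2", mRNA = "#009E73")
  igraph::plot.igraph(
    g, vertex.color = cols[igraph::V(g)$class],
    vertex.size = 4 * vertex_cex, vertex.label.cex = 0.5 * vertex_cex,
    edge.arrow.size = 0.2, ...)
  invisible(x)
}
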