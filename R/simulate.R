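# Synthetic two-group study generator with planted, recoverable truth.
#
# The generator emulates the study design the pipeline is built for: a
# control group and a treated group (n = 3 replicates each, as in a
# triplicated cell-culture experiment), log-normal microarray intensities
# for lncRNA and mRNA probes with planted fold changes, negative-binomial
# miRNA read counts, an annotation with planted genomic-context classes,
# and interaction tables seeded with known sponge triads.

#' Simulation configuration
#'
#' @param n_coding,n_lnc,n_mirna Number of coding genes, lncRNAs and miRNAs.
#' @param n_per_group Replicates per group (default 3, the usual triplicate
#'   cell-culture design).
#' @param effect_grid Planted absolute fold changes (ratios >= 1); planted
#'   features draw their |FC| from this grid. Defaults span the magnitudes
#'   typically reported for array/miRNA-seq hits (1.5-4).
#' @param noise_sd Log2-scale standard deviation of intensity noise
#'   (homoscedastic log-normal error model; default 0.3).
#' @param nb_dispersion Negative-binomial dispersion phi, with
#'   var = mu + phi * mu^2 (default 0.1, a typical biological CV^2 for
#'   replicated small-RNA libraries).
#' @param base_log2_range Range of baseline log2 intensities (uniform).
#' @param lib_size Target miRNA library size per sample.
#' @param de_frac Fraction of features planted as differentially expressed
#'   (split evenly up/down).
#' @param n_triads_forward,n_triads_reverse Planted sponge triads per
#'   direction (forward: lnc up, miRNA down, mRNA up).
#' @param class_probs Named probabilities for lncRNA genomic-context classes
#'   `intergenic`, `natural_antisense`, `intronic_antisense`.
#' @param near_frac Fraction of intergenic lncRNAs planted within the
#'   proximity window of a coding gene.
#' @param background_density Probability of a decoy interaction edge between
#'   eligible (not fully DE-consistent) pairs; 0 = planted edges only.
#' @param window Proximity window in bp (default 300000; pairs are called at
#'   gap < window, strictly).
#' @param chrom_sizes Named chromosome sizes in bp.
#' @param seed Master RNG seed; per-component child seeds are derived from it
#'   by fixed offsets so each stage is independently reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_coding = 300, n_lnc = 300, n_mirna = 200,
                       n_per_group = 3, effect_grid = c(1.5, 2, 3, 4),
                       noise_sd = 0.3, nb_dispersion = 0.1,
                       base_log2_range = c(5, 11), lib_size = 2e5,
                       de_frac = 0.25, n_triads_forward = 6,
                       n_triads_reverse = 4,
                       class_probs = c(intergenic = 0.79,
                                       natural_antisense = 0.12,
                                       intronic_antisense = 0.09),
                       near_frac = 0.5, background_density = 0,
                       window = 300000,
                       chrom_sizes = stats::setNames(rep(200e6, 5),
                                                     paste0("chr", 1:5)),
                       seed = 1L) {
  cfg <- list(n_coding = as.integer(n_coding), n_lnc = as.integer(n_lnc),
              n_mirna = as.integer(n_mirna), n_per_group = as.integer(n_per_group),
              effect_grid = effect_grid, noise_sd = noise_sd,
              nb_dispersion = nb_dispersion, base_log2_range = base_log2_range,
              lib_size = lib_size, de_frac = de_frac,
              n_triads_forward = as.integer(n_triads_forward),
              n_triads_reverse = as.integer(n_triads_reverse),
              class_probs = class_probs, near_frac = near_frac,
              background_density = background_density, window = window,
              chrom_sizes = chrom_sizes, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_coding >= 1, n_lnc >= 1, n_mirna >= 1, n_per_group >= 2,
              all(effect_grid >= 1), noise_sd >= 0, nb_dispersion > 0,
              lib_size > 0, de_frac > 0, de_frac <= 1,
              near_frac >= 0, near_frac <= 1,
              background_density >= 0, background_density <= 1,
              window > 0, all(chrom_sizes > 0))
    stopifnot(setequal(names(class_probs),
                       c("intergenic", "natural_antisense", "intronic_antisense")))
  })
  structure(cfg, class = "sim_config")
}

# Fixed child-seed offsets: each generator stage reseeds independently so a
# stage can be re-run in isolation and still match a full simulate_study().
.child_seed <- function(config, stage) {
  offsets <- c(annotation = 101L, lnc = 211L, mrna = 223L,
               mirna = 307L, interactions = 401L)
  config$seed + offsets[[stage]]
}

.slot_width <- 2e6  # bp per placement slot; >> window so slots never interfere

#' Generate a synthetic annotation with planted lncRNA classes
#'
#' Coding genes (two exons around one intron) are laid out on a fixed grid
#' of 2-Mb slots so that features in different slots are always farther
#' apart than the proximity window. Each lncRNA is planted in one of four
#' configurations with a recorded truth label: intergenic far from every
#' coding gene, intergenic within the window of one coding gene (truth
#' records the exact gap), overlapping a coding exon on the opposite strand
#' (natural antisense), or fully inside a coding intron on the opposite
#' strand (intronic antisense).
#'
#' @param config A [sim_config()].
#' @return `list(features, truth)`: `features` in the [read_gtf()] layout and
#'   `truth` holding `classes`, `proximity_pairs`, `antisense_pairs`, the
#'   planted DE sets/fold-change ratios and planted sponge triads.
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config, "annotation"))
  n_cls <- .class_counts(config)
  n_far  <- n_cls[["intergenic_far"]]
  n_host <- n_cls[["intergenic_near"]] + n_cls[["natural_antisense"]] +
    n_cls[["intronic_antisense"]]
  if (config$n_coding < n_host) {
    stop("generation error: need >= ", n_host, " coding genes to host planted lncRNAs")
  }
  n_slots <- config$n_coding + n_far
  chroms <- names(config$chrom_sizes)
  slots_per_chrom <- floor(config$chrom_sizes / .slot_width)
  if (sum(slots_per_chrom) < n_slots) {
    stop("generation error: chrom_sizes too small for ", n_slots, " placement slots")
  }
  slot_chrom <- rep(chroms, times = pmin(slots_per_chrom, n_slots))[seq_len(n_slots)]
  slot_pos <- unlist(lapply(chroms, function(ch) {
    k <- sum(slot_chrom == ch)
    .slot_width * (seq_len(k) - 1L)
  }))

  gene_len <- 20000L; exon_len <- 5000L
  coding_id <- sprintf("GENE%04d", seq_len(config$n_coding))
  coding_slot <- seq_len(config$n_coding)
  coding_strand <- sample(c("+", "-"), config$n_coding, replace = TRUE)
  g_start <- slot_pos[coding_slot]
  genes <- data.frame(id = coding_id, chrom = slot_chrom[coding_slot],
                      start = g_start, end = g_start + gene_len,
                      strand = coding_strand, biotype = "coding",
                      type = "gene", gene_id = coding_id,
                      stringsAsFactors = FALSE)
  exons <- rbind(
    data.frame(id = paste0(coding_id, ":exon1"), chrom = genes$chrom,
               start = g_start, end = g_start + exon_len,
               strand = coding_strand, biotype = "coding", type = "exon",
               gene_id = coding_id, stringsAsFactors = FALSE),
    data.frame(id = paste0(coding_id, ":exon2"), chrom = genes$chrom,
               start = g_start + gene_len - exon_len, end = g_start + gene_len,
               strand = coding_strand, biotype = "coding", type = "exon",
               gene_id = coding_id, stringsAsFactors = FALSE))

  lnc_id <- sprintf("LNC%04d", seq_len(config$n_lnc))
  classes <- rep(c("intergenic", "intergenic", "natural_antisense", "intronic_antisense"),
                 times = c(n_cls[["intergenic_far"]], n_cls[["intergenic_near"]],
                           n_cls[["natural_antisense"]], n_cls[["intronic_antisense"]]))
  planted <- rep(c("intergenic_far", "intergenic_near", "natural_antisense",
                   "intronic_antisense"),
                 times = n_cls)
  host <- integer(config$n_lnc)          # coding-gene index hosting the lnc, 0 = none
  host[planted != "intergenic_far"] <- sample.int(config$n_coding, n_host)
  far_slots <- config$n_coding + seq_len(n_far)
  far_i <- 0L

  lrows <- vector("list", config$n_lnc)
  prox <- list(); anti <- list()
  for (i in seq_len(config$n_lnc)) {
    cls <- planted[i]
    if (cls == "intergenic_far") {
      far_i <- far_i + 1L
      s <- far_slots[far_i]
      len <- sample(200:20000, 1L)
      st <- slot_pos[s] + 1000000L
      lrows[[i]] <- list(chrom = slot_chrom[s], start = st, end = st + len,
                         strand = sample(c("+", "-"), 1L))
    } else {
      h <- host[i]
      hs <- genes$start[h]; hstr <- genes$strand[h]
      opp <- if (hstr == "+") "-" else "+"
      if (cls == "intergenic_near") {
        gap <- sample(seq(10000L, config$window - 10000L, by = 1000L), 1L)
        len <- sample(200:5000, 1L)
        st <- genes$end[h] + gap
        lrows[[i]] <- list(chrom = genes$chrom[h], start = st, end = st + len,
                           strand = sample(c("+", "-"), 1L))
        prox[[length(prox) + 1L]] <- data.frame(lnc_id = lnc_id[i],
                                                mrna_id = genes$id[h],
                                                distance_bp = gap,
                                                stringsAsFactors = FALSE)
      } else if (cls == "natural_antisense") {
        # overlap exon1 of the host on the opposite strand
        st <- hs + 1000L
        lrows[[i]] <- list(chrom = genes$chrom[h], start = st,
                           end = st + sample(2000:6000, 1L), strand = opp)
        anti[[length(anti) + 1L]] <- data.frame(lnc_id = lnc_id[i],
                                                mrna_id = genes$id[h],
                                                stringsAsFactors = FALSE)
      } else {                                  # intronic_antisense
        # fully inside the intron [hs+5000, hs+15000) on the opposite strand;
        # still a gene-span antisense overlap, so truth records the pair
        st <- hs + 6000L
        lrows[[i]] <- list(chrom = genes$chrom[h], start = st,
                           end = st + sample(1000:8000, 1L), strand = opp)
        anti[[length(anti) + 1L]] <- data.frame(lnc_id = lnc_id[i],
                                                mrna_id = genes$id[h],
                                                stringsAsFactors = FALSE)
      }
    }
  }
  lncs <- data.frame(id = lnc_id,
                     chrom = vapply(lrows, `[[`, "", "chrom"),
                     start = vapply(lrows, function(r) as.numeric(r$start), 0),
                     end = vapply(lrows, function(r) as.numeric(r$end), 0),
                     strand = vapply(lrows, `[[`, "", "strand"),
                     biotype = "lncRNA", type = "gene", gene_id = lnc_id,
                     stringsAsFactors = FALSE)
  features <- rbind(genes, exons, lncs)
  rownames(features) <- NULL

  truth <- list(
    classes = stats::setNames(classes, lnc_id),
    planted_layout = stats::setNames(planted, lnc_id),
    proximity_pairs = if (length(prox)) do.call(rbind, prox) else
      data.frame(lnc_id = character(), mrna_id = character(),
                 distance_bp = numeric(), stringsAsFactors = FALSE),
    antisense_pairs = if (length(anti)) do.call(rbind, anti) else
      data.frame(lnc_id = character(), mrna_id = character(), stringsAsFactors = FALSE),
    ids = list(lnc = lnc_id, mrna = coding_id,
               mirna = sprintf("sim-miR-%03d", seq_len(config$n_mirna)))
  )
  truth <- .plant_de(config, truth)
  list(features = features, truth = truth)
}

.class_counts <- function(config) {
  p <- config$class_probs / sum(config$class_probs)
  n_int <- round(p[["intergenic"]] * config$n_lnc)
  n_nat <- round(p[["natural_antisense"]] * config$n_lnc)
  n_inr <- config$n_lnc - n_int - n_nat
  n_near <- round(config$near_frac * n_int)
  c(intergenic_far = n_int - n_near, intergenic_near = n_near,
    natural_antisense = n_nat, intronic_antisense = n_inr)
}

# Plant per-feature DE ratios (treated/control) and sponge triads.
# Forward triads are consistent by construction: lnc ratio > 1, miRNA
# ratio < 1, mRNA ratio > 1 (reverse triads mirrored).
.plant_de <- function(config, truth) {
  plant_type <- function(ids) {
    n_de <- max(2L, round(config$de_frac * length(ids)))
    n_up <- ceiling(n_de / 2); n_dn <- n_de - n_up
    de <- sample(ids, n_de)
    up <- de[seq_len(n_up)]; dn <- de[n_up + seq_len(n_dn)]
    ratio <- stats::setNames(rep(1, length(ids)), ids)
    ratio[up] <- sample(config$effect_grid, n_up, replace = TRUE)
    ratio[dn] <- 1 / sample(config$effect_grid, n_dn, replace = TRUE)
    list(up = up, down = dn, ratio = ratio)
  }
  lnc <- plant_type(truth$ids$lnc)
  mrna <- plant_type(truth$ids$mrna)
  mirna <- plant_type(truth$ids$mirna)

  nf <- min(config$n_triads_forward, length(lnc$up), length(mirna$down), length(mrna$up))
  nr <- min(config$n_triads_reverse, length(lnc$down), length(mirna$up), length(mrna$down))
  fw <- data.frame(lnc_id = lnc$up[seq_len(nf)], mirna_id = mirna$down[seq_len(nf)],
                   mrna_id = mrna$up[seq_len(nf)], direction = rep("forward", nf),
                   stringsAsFactors = FALSE)
  rv <- data.frame(lnc_id = lnc$down[seq_len(nr)], mirna_id = mirna$up[seq_len(nr)],
                   mrna_id = mrna$down[seq_len(nr)], direction = rep("reverse", nr),
                   stringsAsFactors = FALSE)

  # triad members carry the strongest planted effect: sponge hypotheses are
  # meant to be unambiguous in the truth, so the DE gates (necessary
  # conditions) can recover every planted triad
  strong <- max(config$effect_grid)
  lnc$ratio[fw$lnc_id] <- strong;    mrna$ratio[fw$mrna_id] <- strong
  mirna$ratio[fw$mirna_id] <- 1 / strong
  lnc$ratio[rv$lnc_id] <- 1 / strong; mrna$ratio[rv$mrna_id] <- 1 / strong
  mirna$ratio[rv$mirna_id] <- strong

  truth$de <- list(lnc = lnc, mrna = mrna, mirna = mirna)
  truth$de_lnc_up <- lnc$up;     truth$de_lnc_down <- lnc$down
  truth$de_mrna_up <- mrna$up;   truth$de_mrna_down <- mrna$down
  truth$de_mirna_up <- mirna$up; truth$de_mirna_down <- mirna$down
  truth$planted_triads <- rbind(fw, rv)
  # triad members are planted as well-expressed transcripts: sponge lncRNAs
  # must clear the raw-intensity gate, and all planted array features sit in
  # the interior of the intensity distribution where quantile normalization
  # preserves fold changes
  truth$high_expr_lnc <- unique(truth$planted_triads$lnc_id)
  truth$high_expr_mrna <- unique(truth$planted_triads$mrna_id)
  truth$seeds <- vapply(c("annotation", "lnc", "mrna", "mirna", "interactions"),
                        function(s) .child_seed(config, s), 0L)
  truth
}

#' Generate a planted-fold-change expression matrix
#'
#' Log2 intensity is `base + I(treated) * log2(ratio) + N(0, noise_sd)`,
#' exponentiated back to the linear scale; non-planted features have ratio 1.
#' Baselines are uniform on `base_log2_range`, except lncRNAs participating
#' in planted triads, which get baselines >= log2(400) so they clear the
#' raw-intensity > 100 sponge gate by design.
#'
#' @param config A [sim_config()].
#' @param truth Truth list from [gen_annotation()].
#' @param type `"lnc"` or `"mrna"` (which probe set to emit).
#' @return Linear-scale matrix (features x samples) with a `"groups"`
#'   attribute (`control` / `C+T`).
#' @export
gen_expression <- function(config, truth, type = c("lnc", "mrna")) {
  stopifnot(inherits(config, "sim_config"))
  type <- match.arg(type)
  set.seed(.child_seed(config, type))
  ids <- truth$ids[[type]]
  n <- config$n_per_group
  ratio <- truth$de[[type]]$ratio[ids]
  base <- stats::runif(length(ids), config$base_log2_range[1], config$base_log2_range[2])
  # triad members must clear the raw-intensity > 100 gate (lncRNAs) and are
  # kept inside the bulk of the intensity distribution: features at the
  # extreme ranks of every sample are flattened by quantile normalization
  # (rank compression), a property of the method, not of the planted biology
  hi_set <- if (type == "lnc") truth$high_expr_lnc else truth$high_expr_mrna
  if (length(hi_set)) {
    hi <- ids %in% hi_set
    base[hi] <- stats::runif(sum(hi), log2(400), 9.3)
  }
  mu <- cbind(matrix(base, length(ids), n),
              matrix(base + log2(ratio), length(ids), n))
  noise <- matrix(stats::rnorm(length(mu), 0, config$noise_sd), nrow(mu), ncol(mu))
  m <- 2^(mu + noise)
  rownames(m) <- ids
  colnames(m) <- c(paste0("ctrl_", seq_len(n)), paste0("trt_", seq_len(n)))
  attr(m, "groups") <- stats::setNames(rep(c("control", "C+T"), each = n), colnames(m))
  m
}

#' Generate negative-binomial miRNA read counts
#'
#' Counts are `NB(mean = lib_size * pi_i * ratio_i^I(treated),
#' dispersion = phi)` with feature abundances `pi_i` drawn log-normally and
#' normalized to sum to one, so expected library size is `lib_size` in the
#' control group. With `phi -> 0` the model tends to Poisson.
#'
#' @inheritParams gen_expression
#' @return Integer count matrix with a `"groups"` attribute.
#' @export
gen_mirna_counts <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config, "mirna"))
  ids <- truth$ids$mirna
  n <- config$n_per_group
  ratio <- truth$de$mirna$ratio[ids]
  w <- stats::rlnorm(length(ids), meanlog = 0, sdlog = 1)
  pi_i <- w / sum(w)
  mu <- cbind(matrix(config$lib_size * pi_i, length(ids), n),
              matrix(config$lib_size * pi_i * ratio, length(ids), n))
  m <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
              nrow(mu), ncol(mu))
  rownames(m) <- ids
  colnames(m) <- c(paste0("ctrl_", seq_len(n)), paste0("trt_", seq_len(n)))
  attr(m, "groups") <- stats::setNames(rep(c("control", "C+T"), each = n), colnames(m))
  m
}

#' Generate interaction tables seeded with the planted triads
#'
#' Every planted (lnc, miRNA) binding edge and (miRNA, mRNA) target edge is
#' always present, so the DE gates can never drop a planted triad (recall 1
#' by construction). Decoy edges are added at `background_density` among
#' pairs in which at least one endpoint is not differentially expressed, so
#' decoys can never assemble into a spurious fully-DE-consistent triad.
#' The co-expression table carries planted correlations (|r| uniform on
#' \[0.6, 0.8\], sign matching the planted fold-change product) for the
#' planted proximity pairs, plus uniform background correlations.
#'
#' @inheritParams gen_expression
#' @return Named list of `interaction_table`s: `binding`, `targets`,
#'   `coexpression`, `disease`.
#' @export
gen_interactions <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.child_seed(config, "interactions"))
  tri <- truth$planted_triads
  de_lnc <- c(truth$de_lnc_up, truth$de_lnc_down)
  de_mir <- c(truth$de_mirna_up, truth$de_mirna_down)
  de_mrna <- c(truth$de_mrna_up, truth$de_mrna_down)

  bind <- data.frame(source_id = tri$lnc_id, target_id = tri$mirna_id,
                     sites = sample(1:22, nrow(tri), replace = TRUE),
                     stringsAsFactors = FALSE)
  targ <- data.frame(source_id = tri$mirna_id, target_id = tri$mrna_id,
                     stringsAsFactors = FALSE)

  decoys <- function(src_ids, tgt_ids, src_de, tgt_de, existing) {
    if (config$background_density <= 0) {
      return(data.frame(source_id = character(), target_id = character(),
                        stringsAsFactors = FALSE))
    }
    all_pairs <- expand.grid(source_id = src_ids, target_id = tgt_ids,
                             stringsAsFactors = FALSE)
    eligible <- !(all_pairs$source_id %in% src_de & all_pairs$target_id %in% tgt_de)
    key <- paste(all_pairs$source_id, all_pairs$target_id)
    eligible <- eligible & !(key %in% paste(existing$source_id, existing$target_id))
    pick <- eligible & stats::runif(nrow(all_pairs)) < config$background_density
    all_pairs[pick, , drop = FALSE]
  }

  bd <- decoys(truth$ids$lnc, truth$ids$mirna, de_lnc, de_mir, bind)
  if (nrow(bd)) bd$sites <- sample(1:5, nrow(bd), replace = TRUE)
  bind <- rbind(bind, bd)
  td <- decoys(truth$ids$mirna, truth$ids$mrna, de_mir, de_mrna, targ)
  targ <- rbind(targ, td)

  prox <- truth$proximity_pairs
  if (nrow(prox)) {
    fcprod <- sign(log(truth$de$lnc$ratio[prox$lnc_id]) *
                     log(truth$de$mrna$ratio[prox$mrna_id]))
    fcprod[fcprod == 0] <- 1
    r <- fcprod * stats::runif(nrow(prox), 0.6, 0.8)
    coex <- data.frame(source_id = prox$lnc_id, target_id = prox$mrna_id,
                       r = r, stringsAsFactors = FALSE)
  } else {
    coex <- data.frame(source_id = character(), target_id = character(),
                       r = numeric(), stringsAsFactors = FALSE)
  }
  cd <- decoys(truth$ids$lnc, truth$ids$mrna, de_lnc, de_mrna, coex)
  if (nrow(cd)) cd$r <- stats::runif(nrow(cd), -1, 1)
  coex <- rbind(coex, cd)

  dis_lnc <- utils::head(de_lnc, max(1L, length(de_lnc) %/% 3L))
  dis <- data.frame(source_id = dis_lnc,
                    target_id = sample(truth$ids$mrna, length(dis_lnc), replace = TRUE),
                    disease = sample(c("cardiovascular", "cancer"),
                                     length(dis_lnc), replace = TRUE),
                    stringsAsFactors = FALSE)
  dis <- dis[!duplicated(paste(dis$source_id, dis$target_id)), , drop = FALSE]

  list(
    binding = interaction_table(bind$source_id, bind$target_id, bind$sites,
                                "lnc_mirna_binding"),
    targets = interaction_table(targ$source_id, targ$target_id,
                                rep("validated", nrow(targ)), "mirna_mrna_target"),
    coexpression = interaction_table(coex$source_id, coex$target_id, coex$r,
                                     "lnc_mrna_coexpression"),
    disease = interaction_table(dis$source_id, dis$target_id, dis$disease,
                                "lnc_disease")
  )
}

#' Run the full generator
#'
#' @param config A [sim_config()].
#' @return List with `features`, `lnc_expr`, `mrna_expr`, `mirna_counts`,
#'   `tables` (see [gen_interactions()]) and `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  ann <- gen_annotation(config)
  list(features = ann$features,
       lnc_expr = gen_expression(config, ann$truth, "lnc"),
       mrna_expr = gen_expression(config, ann$truth, "mrna"),
       mirna_counts = gen_mirna_counts(config, ann$truth),
       tables = gen_interactions(config, ann$truth),
       truth = ann$truth,
       config = config)
}

#' Write a simulated study to disk
#'
#' Emits every artifact through the package's own writers (GTF annotation,
#' TSV matrices and interaction tables, JSON truth bundle), so reading them
#' back exercises the full IO round trip.
#'
#' @param sim Result of [simulate_study()].
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_gtf(sim$features, p("annotation.gtf"))
  write_expression_tsv(sim$lnc_expr, p("lnc_expression.tsv"))
  write_expression_tsv(sim$mrna_expr, p("mrna_expression.tsv"))
  write_expression_tsv(sim$mirna_counts, p("mirna_counts.tsv"))
  write_interactions_tsv(sim$tables$binding, p("lnc_mirna_binding.tsv"))
  write_interactions_tsv(sim$tables$targets, p("mirna_mrna_targets.tsv"))
  write_interactions_tsv(sim$tables$coexpression, p("lnc_mrna_coexpression.tsv"))
  write_interactions_tsv(sim$tables$disease, p("lnc_disease.tsv"))
  groups <- sample_groups(sim$lnc_expr)
  .write_tsv(data.frame(sample_id = names(groups), group = unname(groups)),
             p("groups.tsv"))
  truth <- sim$truth
  truth$de <- lapply(truth$de, function(x) list(up = x$up, down = x$down,
                                                ratio = as.list(x$ratio)))
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
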