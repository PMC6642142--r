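# End-to-end orchestration: simulate (or load) -> normalize -> DE ->
# genomic context -> association -> ceRNA network -> enrichment ->
# validation statistics, with a machine-readable run manifest.

#' Pipeline configuration
#'
#' Collects every tunable threshold of the integrated analysis in one
#' validated object. Thresholds default to the conventional gates:
#' |FC| >= 1.5 and p <= 0.05 for differential expression, a 300-kb
#' proximity window, raw intensity > 100 for sponge candidates, and a
#' 0.6-0.8 co-expression magnitude band.
#'
#' @param sim A [sim_config()] describing the synthetic study to generate;
#'   ignored when `input_dir` is given.
#' @param input_dir Optional directory of pre-existing inputs in the
#'   [write_simulation()] layout; when given, the simulate stage loads
#'   instead of generating.
#' @param fc_min,p_max Differential-expression gates.
#' @param window Proximity window (bp).
#' @param intensity_min Raw-intensity sponge gate.
#' @param r_min,r_max Co-expression magnitude band.
#' @param concordance_mode `"sign_concordant"` or `"any"`.
#' @param seed Seed for the pipeline's own randomness (gene-set
#'   construction for the enrichment stage).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), input_dir = NULL,
                            fc_min = 1.5, p_max = 0.05, window = 300000,
                            intensity_min = 100, r_min = 0.6, r_max = 0.8,
                            concordance_mode = "sign_concordant", seed = 1L) {
  if (!(fc_min >= 1)) stop("invalid fc_min: must be >= 1")
  if (!(p_max > 0 && p_max <= 1)) stop("invalid p_max: must be in (0, 1]")
  if (!(window > 0)) stop("invalid window: must be > 0")
  if (!(intensity_min >= 0)) stop("invalid intensity_min: must be >= 0")
  if (!(r_min >= 0 && r_max <= 1 && r_min <= r_max)) {
    stop("invalid co-expression band: need 0 <= r_min <= r_max <= 1")
  }
  concordance_mode <- match.arg(concordance_mode, c("sign_concordant", "any"))
  if (!is.null(input_dir)) {
    need <- file.path(input_dir,
                      c("annotation.gtf", "lnc_expression.tsv", "mrna_expression.tsv",
                        "mirna_counts.tsv", "lnc_mirna_binding.tsv",
                        "mirna_mrna_targets.tsv", "lnc_mrna_coexpression.tsv",
                        "lnc_disease.tsv", "groups.tsv"))
    missing <- need[!file.exists(need)]
    if (length(missing)) stop("missing input file(s): ", paste(missing, collapse = ", "))
  } else {
    stopifnot(inherits(sim, "sim_config"))
  }
  structure(list(sim = sim, input_dir = input_dir, fc_min = fc_min,
                 p_max = p_max, window = window, intensity_min = intensity_min,
                 r_min = r_min, r_max = r_max,
                 concordance_mode = concordance_mode, seed = as.integer(seed)),
            class = "pipeline_config")
}

.load_inputs <- function(dir) {
  gmap <- .read_tsv(file.path(dir, "groups.tsv"))
  group_map <- stats::setNames(gmap$group, gmap$sample_id)
  list(features = read_gtf(file.path(dir, "annotation.gtf")),
       lnc_expr = read_expression_tsv(file.path(dir, "lnc_expression.tsv"), group_map),
       mrna_expr = read_expression_tsv(file.path(dir, "mrna_expression.tsv"), group_map),
       mirna_counts = read_counts_tsv(file.path(dir, "mirna_counts.tsv"), group_map),
       tables = list(
         binding = read_interactions_tsv(file.path(dir, "lnc_mirna_binding.tsv"),
                                         "lnc_mirna_binding"),
         targets = read_interactions_tsv(file.path(dir, "mirna_mrna_targets.tsv"),
                                         "mirna_mrna_target"),
         coexpression = read_interactions_tsv(file.path(dir, "lnc_mrna_coexpression.tsv"),
                                              "lnc_mrna_coexpression"),
         disease = read_interactions_tsv(file.path(dir, "lnc_disease.tsv"),
                                         "lnc_disease")),
       truth = NULL)
}

#' Run the integrated pipeline
#'
#' Executes all eight stages in order, writing each stage's outputs as TSV
#' under `outdir` and a `manifest.json` recording, per stage, the
#' parameters used, the files written with row counts, and their md5
#' hashes. The manifest contains no timestamps or absolute paths, so a
#' rerun with the same configuration is byte-identical. Any stage failure
#' aborts with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created; existing files overwritten).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  written <- character()
  emit <- function(stage, params, files) {
    counts <- vapply(files, function(f) {
      if (grepl("\\.tsv$", f)) nrow(.read_tsv(file.path(outdir, f)))
      else NA_integer_
    }, 0L)
    manifest[[length(manifest) + 1L]] <<- list(
      stage = stage, parameters = params,
      outputs = lapply(seq_along(files), function(i) {
        list(path = files[[i]], rows = counts[[i]],
             md5 = unname(tools::md5sum(file.path(outdir, files[[i]]))))
      }))
    written <<- c(written, files)
  }
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  p <- function(f) file.path(outdir, f)
  filt <- de_filter(fc_min = config$fc_min, p_max = config$p_max)

  ## 1 simulate (or load)
  run_stage("simulate", function() {
    if (is.null(config$input_dir)) {
      sim <- simulate_study(config$sim)
      write_simulation(sim, p("inputs"))
      results$inputs <<- sim
    } else {
      results$inputs <<- .load_inputs(config$input_dir)
    }
    emit("simulate",
         list(source = if (is.null(config$input_dir)) "generator" else "files",
              seed = if (is.null(config$input_dir)) config$sim$seed else NA),
         if (is.null(config$input_dir))
           file.path("inputs", c("annotation.gtf", "lnc_expression.tsv",
                                 "mrna_expression.tsv", "mirna_counts.tsv",
                                 "lnc_mirna_binding.tsv", "mirna_mrna_targets.tsv",
                                 "lnc_mrna_coexpression.tsv", "lnc_disease.tsv",
                                 "groups.tsv", "truth.json"))
         else character())
  })
  inp <- results$inputs

  ## 2 normalize
  run_stage("normalize", function() {
    results$lnc_norm <<- quantile_normalize(inp$lnc_expr)
    results$mrna_norm <<- quantile_normalize(inp$mrna_expr)
    write_expression_tsv(results$lnc_norm, p("lnc_normalized.tsv"))
    write_expression_tsv(results$mrna_norm, p("mrna_normalized.tsv"))
    emit("normalize", list(method = "quantile"),
         c("lnc_normalized.tsv", "mrna_normalized.tsv"))
  })

  ## 3 differential expression
  run_stage("diffexpr", function() {
    results$lnc_de <<- ttest_de(results$lnc_norm, filter = filt)
    results$mrna_de <<- ttest_de(results$mrna_norm, filter = filt)
    results$mirna_de <<- nb_exact_de(inp$mirna_counts, filter = filt)
    write_de_tsv(results$lnc_de, p("lnc_de.tsv"))
    write_de_tsv(results$mrna_de, p("mrna_de.tsv"))
    write_de_tsv(results$mirna_de, p("mirna_de.tsv"))
    emit("diffexpr",
         list(fc_min = config$fc_min, p_max = config$p_max,
              intensity_method = "ttest on log2(x + 1)", count_method = "nb_exact"),
         c("lnc_de.tsv", "mrna_de.tsv", "mirna_de.tsv"))
  })

  ## 4 genomic context
  run_stage("context", function() {
    classes <- classify_lncrnas(inp$features)
    results$classes <<- classes
    sig_lnc <- unlist(apply_de_filter(results$lnc_de, filt), use.names = FALSE)
    sig_mrna <- unlist(apply_de_filter(results$mrna_de, filt), use.names = FALSE)
    lnc_g <- inp$features[inp$features$type == "gene" &
                            inp$features$id %in% sig_lnc, , drop = FALSE]
    mrna_g <- inp$features[inp$features$type == "gene" &
                             inp$features$id %in% sig_mrna, , drop = FALSE]
    results$prox <<- proximity_pairs(lnc_g, mrna_g, window = config$window)
    results$anti <<- antisense_pairs(lnc_g, mrna_g)
    sm <- summarize_lncrna(inp$features, classes)
    .write_tsv(results$prox, p("proximity_pairs.tsv"))
    .write_tsv(results$anti, p("antisense_pairs.tsv"))
    .write_tsv(data.frame(lnc_id = names(classes), class = unname(classes)),
               p("lnc_classes.tsv"))
    .write_tsv(sm$by_class, p("lnc_class_summary.tsv"))
    emit("context", list(window = config$window),
         c("proximity_pairs.tsv", "antisense_pairs.tsv", "lnc_classes.tsv",
           "lnc_class_summary.tsv"))
  })

  ## 5 association
  run_stage("associate", function() {
    results$concordant <<- concordance_filter(
      results$lnc_de, results$mrna_de, inp$tables$coexpression,
      r_min = config$r_min, r_max = config$r_max, mode = config$concordance_mode)
    results$disease <<- disease_join(results$lnc_de, inp$tables$disease)
    .write_tsv(results$concordant, p("concordant_pairs.tsv"))
    .write_tsv(results$disease, p("disease_associations.tsv"))
    emit("associate",
         list(r_min = config$r_min, r_max = config$r_max,
              mode = config$concordance_mode),
         c("concordant_pairs.tsv", "disease_associations.tsv"))
  })

  ## 6 ceRNA network
  run_stage("cerna", function() {
    whitelist <- inp$features$id[inp$features$type == "gene" &
                                   inp$features$biotype == "lncRNA"]
    up <- select_sponge_lncrnas(results$lnc_de, "up",
                                intensity_min = config$intensity_min,
                                whitelist = whitelist)
    dn <- select_sponge_lncrnas(results$lnc_de, "down",
                                intensity_min = 0, whitelist = NULL)
    fw <- build_sponge_triads(up, results$mirna_de, results$mrna_de,
                              inp$tables$binding, inp$tables$targets,
                              direction = "up", lnc_de = results$lnc_de)
    rv <- build_sponge_triads(dn, results$mirna_de, results$mrna_de,
                              inp$tables$binding, inp$tables$targets,
                              direction = "down", lnc_de = results$lnc_de)
    results$triads_forward <<- fw
    results$triads_reverse <<- rv
    .write_tsv(as.data.frame(fw), p("triads_forward.tsv"))
    .write_tsv(as.data.frame(rv), p("triads_reverse.tsv"))
    if (nrow(fw) + nrow(rv) > 0) {
      net <- assemble_network(if (nrow(fw)) fw, if (nrow(rv)) rv)
      results$network <<- net
      write_network(net, p("network_nodes.tsv"), p("network_edges.tsv"))
      .write_tsv(network_stats(net), p("network_stats.tsv"))
      files <- c("triads_forward.tsv", "triads_reverse.tsv", "network_nodes.tsv",
                 "network_edges.tsv", "network_stats.tsv")
    } else {
      warning("cerna: no triads survived the gates")
      files <- c("triads_forward.tsv", "triads_reverse.tsv")
    }
    emit("cerna", list(intensity_min = config$intensity_min,
                       whitelist = "annotation lncRNAs"), files)
  })

  ## 7 enrichment
  run_stage("enrich", function() {
    universe <- results$mrna_de$feature_id
    sig_up <- apply_de_filter(results$mrna_de, filt)$up
    set.seed(config$seed + 509L)
    sets <- .toy_gene_sets(universe, sig_up)
    ora <- hypergeom_ora(sig_up, universe, sets)
    results$enrichment <<- ora
    .write_tsv(ora, p("enrichment.tsv"))
    emit("enrich", list(universe = "assayed mRNAs", n_sets = length(sets)),
         "enrichment.tsv")
  })

  ## 8 validation statistics
  run_stage("validate", function() {
    groups <- attr(inp$lnc_expr, "groups")
    target <- if (!is.null(inp$truth) && nrow(inp$truth$planted_triads)) {
      inp$truth$planted_triads$lnc_id[1L]
    } else rownames(inp$lnc_expr)[1L]
    vals <- inp$lnc_expr[target, ]
    glist <- split(unname(vals / mean(vals[groups == groups[[1L]]])), groups)
    kw <- kruskal_wallis(glist)
    dn <- dunn_posthoc(glist)
    rf <- relative_fold(glist, reference = groups[[1L]])
    results$validation <<- list(feature = target, kruskal_wallis = kw,
                                dunn = dn, fold = rf)
    .write_tsv(data.frame(feature = target, H = kw$H, df = kw$df, p = kw$p),
               p("validation_kw.tsv"))
    .write_tsv(dn, p("validation_dunn.tsv"))
    .write_tsv(rf, p("validation_fold.tsv"))
    emit("validate", list(feature = target, reference = groups[[1L]]),
         c("validation_kw.tsv", "validation_dunn.tsv", "validation_fold.tsv"))
  })

  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest, outdir = outdir)))
}

# Deterministic toy gene-set collection for the enrichment stage: random
# background sets plus one set enriched in the supplied signature.
.toy_gene_sets <- function(universe, signature, n_sets = 10L, set_size = 25L) {
  set_size <- min(set_size, max(2L, length(universe) %/% 2L))
  sets <- lapply(seq_len(n_sets), function(i) sample(universe, set_size))
  names(sets) <- sprintf("SET%02d", seq_len(n_sets))
  if (length(signature)) {
    k <- min(length(signature), set_size)
    sets[["SIGNATURE"]] <- unique(c(utils::head(signature, k),
                                    sample(universe, set_size - k)))
  }
  sets
}
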