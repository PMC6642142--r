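# External-evidence filters for lncRNA-mRNA candidate pairs: co-expression
# concordance against a reference correlation table and disease-annotation
# joins.

#' Filter candidate pairs by reference co-expression concordance
#'
#' Keeps a (lncRNA, mRNA) pair iff both members are significantly
#' differentially expressed, the reference correlation magnitude lies in
#' `[r_min, r_max]` (the band check is on |r|, so strong negative
#' co-expression also qualifies), and — in `sign_concordant` mode — the sign
#' of r matches the sign of the product of the two signed fold changes
#' (positively co-expressed partners must move together, negatively
#' co-expressed partners must move apart). `mode = "any"` skips the sign
#' check and only enforces the band, so its output is always a superset.
#'
#' @param lnc_de,mrna_de `de_table`s for lncRNAs and mRNAs.
#' @param coexpr_table An `interaction_table` of kind
#'   `lnc_mrna_coexpression`.
#' @param r_min,r_max Inclusive correlation-magnitude band (defaults 0.6 and
#'   0.8).
#' @param mode `"sign_concordant"` (default) or `"any"`.
#' @return Data frame `lnc_id`, `mrna_id`, `r`, `lnc_fc`, `mrna_fc`,
#'   `concordant`.
#' @export
concordance_filter <- function(lnc_de, mrna_de, coexpr_table,
                               r_min = 0.6, r_max = 0.8,
                               mode = c("sign_concordant", "any")) {
  mode <- match.arg(mode)
  stopifnot(inherits(lnc_de, "de_table"), inherits(mrna_de, "de_table"))
  if (interaction_kind(coexpr_table) != "lnc_mrna_coexpression") {
    stop("coexpr_table must have kind lnc_mrna_coexpression")
  }
  sig_l <- lnc_de[lnc_de$direction != "flat", , drop = FALSE]
  sig_m <- mrna_de[mrna_de$direction != "flat", , drop = FALSE]
  tab <- as.data.frame(coexpr_table)
  tab <- tab[tab$source_id %in% sig_l$feature_id &
               tab$target_id %in% sig_m$feature_id, , drop = FALSE]
  tab <- tab[abs(tab$r) >= r_min & abs(tab$r) <= r_max, , drop = FALSE]
  lnc_fc <- sig_l$signed_fc[match(tab$source_id, sig_l$feature_id)]
  mrna_fc <- sig_m$signed_fc[match(tab$target_id, sig_m$feature_id)]
  concordant <- sign(tab$r) == sign(lnc_fc * mrna_fc)
  out <- data.frame(lnc_id = tab$source_id, mrna_id = tab$target_id,
                    r = tab$r, lnc_fc = lnc_fc, mrna_fc = mrna_fc,
                    concordant = concordant, stringsAsFactors = FALSE)
  if (mode == "sign_concordant") out <- out[out$concordant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Join significant lncRNAs to disease annotations
#'
#' Inner join of significantly differentially expressed lncRNAs against a
#' lncRNA-disease table, optionally restricted to a set of disease labels
#' (e.g. cardiovascular). An empty join is a valid (empty) result.
#'
#' @param lnc_de A `de_table` for lncRNAs.
#' @param disease_table An `interaction_table` of kind `lnc_disease`.
#' @param disease_filter Optional character vector of disease labels to
#'   keep.
#' @return Data frame `lnc_id`, `mrna_id`, `disease`, `lnc_fc`, `direction`.
#' @export
disease_join <- function(lnc_de, disease_table, disease_filter = NULL) {
  stopifnot(inherits(lnc_de, "de_table"))
  if (interaction_kind(disease_table) != "lnc_disease") {
    stop("disease_table must have kind lnc_disease")
  }
  sig <- lnc_de[lnc_de$direction != "flat", , drop = FALSE]
  tab <- as.data.frame(disease_table)
  tab <- tab[tab$source_id %in% sig$feature_id, , drop = FALSE]
  if (!is.null(disease_filter)) {
    tab <- tab[tab$disease %in% disease_filter, , drop = FALSE]
  }
  i <- match(tab$source_id, sig$feature_id)
  out <- data.frame(lnc_id = tab$source_id, mrna_id = tab$target_id,
                    disease = tab$disease, lnc_fc = sig$signed_fc[i],
                    direction = sig$direction[i], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
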