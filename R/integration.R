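#' Annotate target predictions with disease-relevance scores
#'
#' Maps each predicted protein target to its gene symbol and attaches the
#' gene's inference score for the requested disease (CTD-style: a
#' text-mining-derived strength of the gene-disease association). Targets
#' without a gene mapping are flagged `unmapped` and score 0; genes without
#' a link to the requested disease score 0.
#'
#' @param predictions Data.frame from [predict_targets()].
#' @param links Disease-gene link data.frame ([read_disease_links()]).
#' @param gene_protein_map Named character vector, `target_id` ->
#'   `gene_symbol`.
#' @param disease_id The disease to scope the annotation to (required: the
#'   method is general, no disease is hardcoded).
#' @return `predictions` with columns `gene_symbol`,
#'   `disease_inference_score`, `unmapped` added.
#' @export
annotate_disease_relevance <- function(predictions, links, gene_protein_map,
                                       disease_id) {
  if (missing(disease_id) || is.null(disease_id))
    stop("disease_id is required")
  genes <- unname(gene_protein_map[predictions$target_id])
  unmapped <- is.na(genes)
  if (all(unmapped))
    stop("gene-protein map covers none of the predicted targets")
  dl <- links[links$disease_id == disease_id, , drop = FALSE]
  if (nrow(dl) == 0L)
    warning("disease '", disease_id,
            "' absent from the link table; all inference scores 0")
  score_by_gene <- if (nrow(dl) > 0)
    tapply(dl$inference_score, dl$gene_symbol, max) else numeric(0)
  sc <- as.numeric(score_by_gene[genes])
  sc[is.na(sc)] <- 0
  predictions$gene_symbol <- genes
  predictions$disease_inference_score <- sc
  predictions$unmapped <- unmapped
  predictions
}

#' Build the integrated compound-selection report
#'
#' Joins the three evidence layers side by side — connectivity scores and
#' ranks, predicted targets with their disease-relevance annotation, and the
#' approved-drug (therapeutic) flag — into one record per scored instance.
#' Instances without a usable structure keep an empty prediction list and
#' are never dropped; connectivity values pass through bit-identical. No
#' meta-score is invented: the layers are reported for the user to weigh.
#'
#' @param connectivity_table Ranked data.frame from [rank_instances()].
#' @param predictions Annotated predictions ([annotate_disease_relevance()]),
#'   or `NULL` for a connectivity-only report.
#' @param compounds Compound table ([read_compound_table()]) keyed by
#'   `instance_id`.
#' @param sort_by `"positive"` (default, strongest mimics first) or
#'   `"negative"` (strongest reversers first).
#' @return A data.frame with one row per instance: connectivity columns,
#'   `compound_id`, `therapeutic_flag`, and `predicted_targets` — the
#'   per-compound target list serialized as
#'   `target:score:support_nM:disease_score` items joined by `;`.
#' @export
build_report <- function(connectivity_table, predictions, compounds,
                         sort_by = c("positive", "negative")) {
  sort_by <- match.arg(sort_by)
  if (nrow(connectivity_table) < 1L) stop("connectivity table is empty")
  if (anyDuplicated(connectivity_table$source_id))
    stop("join error: duplicate instance ids in connectivity table")
  if (anyDuplicated(compounds$instance_id))
    stop("join error: duplicate instance ids in compound table")
  ix <- match(connectivity_table$source_id, compounds$instance_id)
  out <- connectivity_table
  out$compound_id <- compounds$compound_id[ix]
  out$therapeutic_flag <- compounds$therapeutic_flag[ix]
  fmt <- function(cid) {
    if (is.na(cid) || is.null(predictions)) return("")
    p <- predictions[predictions$compound_id == cid, , drop = FALSE]
    if (nrow(p) == 0L) return("")
    p <- p[order(p$rank), , drop = FALSE]
    sup <- if ("experimental_support_nM" %in% names(p))
      p$experimental_support_nM else rep(NA_real_, nrow(p))
    dis <- if ("disease_inference_score" %in% names(p))
      p$disease_inference_score else rep(NA_real_, nrow(p))
    paste(sprintf("%s:%.4f:%s:%s", p$target_id, p$score,
                  ifelse(is.na(sup), "NA", format(sup, trim = TRUE)),
                  ifelse(is.na(dis), "NA", format(dis, trim = TRUE))),
          collapse = ";")
  }
  out$predicted_targets <- vapply(out$compound_id, fmt, character(1),
                                  USE.NAMES = FALSE)
  ord <- if (sort_by == "positive") order(out$rank_positive)
         else order(out$rank_negative)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
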