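#' Collapse probe-level expression to gene level
#'
#' Multiple microarray probes mapping to one gene symbol are reduced to a
#' single row before ranking. The default (`mode = "max"`) takes each gene's
#' per-sample value as the maximum across its probes, mirroring GSEA's
#' `max_probe` collapse; `"mean"` averages instead. Probes absent from the
#' map are dropped and counted.
#'
#' @param profile An [expression_profile()] at probe level.
#' @param map A [probe_map()].
#' @param mode `"max"` (default) or `"mean"`.
#' @return A gene-level [expression_profile()] (one row per distinct mapped
#'   symbol, symbols sorted) with attribute `n_unmapped`.
#' @export
collapse_probes <- function(profile, map, mode = c("max", "mean")) {
  stopifnot(inherits(profile, "expression_profile"))
  mode <- match.arg(mode)
  symbols <- unclass(map)[rownames(profile)]
  mapped <- !is.na(symbols)
  n_unmapped <- sum(!mapped)
  if (!any(mapped))
    stop("collapse error: zero probes map to a gene symbol")
  m <- unclass(profile)[mapped, , drop = FALSE]
  sym <- symbols[mapped]
  grp <- factor(sym, levels = sort(unique(sym)))
  fun <- if (mode == "max") max else mean
  collapsed <- do.call(rbind, lapply(split(seq_len(nrow(m)), grp), function(ix) {
    if (length(ix) == 1L) m[ix, ] else apply(m[ix, , drop = FALSE], 2, fun)
  }))
  out <- expression_profile(collapsed, probe_ids = levels(grp),
                            sample_ids = colnames(m))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# GSEA variance floor: each class sd is floored at 0.2 * |class mean|,
# with an absolute floor of 0.2 when the mean is 0.
.s2n_sd <- function(s, m) {
  floor_ <- ifelse(m == 0, 0.2, 0.2 * abs(m))
  pmax(s, floor_)
}

#' Rank genes by two-class differential expression
#'
#' Computes a per-gene ranking metric oriented as first-CLS-class minus
#' second (so for an `ESC HRT` phenotype file positive values are
#' stem-cell-high genes) and returns genes sorted by the metric, most
#' upregulated first. Ties are broken by gene symbol (ascending) so the
#' ordering is reproducible across runs and platforms.
#'
#' `signal2noise` is (mean_A - mean_B) / (sd_A + sd_B) with the GSEA
#' variance floor applied to each class standard deviation (floored at
#' 0.2 x |class mean|; 0.2 when the mean is 0) and needs at least 3 samples
#' per class. `log2_ratio_of_classes` is log2(mean_A / mean_B) on linear
#' data, or the difference of class means when `logged = TRUE`; a gene whose
#' class means are both 0 gets metric 0.
#'
#' @param profile A gene-level [expression_profile()].
#' @param phen A [phenotype_assignment()] with exactly 2 classes used.
#' @param metric `"signal2noise"` (default) or `"log2_ratio_of_classes"`.
#' @param logged Set `TRUE` when expression values are already on log2
#'   scale (common for GEO matrices); affects only the ratio metric.
#' @return A [ranked_genes()] object.
#' @export
differential_ranking <- function(profile, phen,
                                 metric = c("signal2noise",
                                            "log2_ratio_of_classes"),
                                 logged = FALSE) {
  stopifnot(inherits(profile, "expression_profile"),
            inherits(phen, "phenotype_assignment"))
  metric <- match.arg(metric)
  used <- sort(unique(phen$assignment))
  if (length(used) != 2L)
    stop(sprintf("class-count error: differential ranking needs exactly 2 classes, found %d",
                 length(used)))
  if (length(phen$assignment) != ncol(profile))
    stop("phenotype assignment length does not match sample count")
  a <- phen$assignment == used[1]
  b <- phen$assignment == used[2]
  m <- unclass(profile)
  mA <- rowMeans(m[, a, drop = FALSE]); mB <- rowMeans(m[, b, drop = FALSE])
  if (metric == "signal2noise") {
    if (sum(a) < 3L || sum(b) < 3L)
      stop("signal2noise requires at least 3 samples per class")
    sA <- .s2n_sd(apply(m[, a, drop = FALSE], 1, stats::sd), mA)
    sB <- .s2n_sd(apply(m[, b, drop = FALSE], 1, stats::sd), mB)
    vals <- (mA - mB) / (sA + sB)
  } else {
    if (logged) {
      vals <- mA - mB
    } else {
      both_zero <- mA == 0 & mB == 0
      if (any((mA <= 0 | mB <= 0) & !both_zero))
        stop("log2_ratio_of_classes on linear data requires positive class means; ",
             "use logged = TRUE for pre-logged matrices")
      vals <- numeric(length(mA))
      ok <- !both_zero
      vals[ok] <- log2(mA[ok] / mB[ok])  # both-zero genes stay at metric 0
    }
  }
  ord <- order(-vals, rownames(m))
  ranked_genes(rownames(m)[ord], vals[ord], metric_name = metric)
}

#' Rank genes of a compound treatment against its vehicle control
#'
#' The per-gene metric is log2(mean treatment / mean vehicle) — the metric
#' used to order each compound instance's genes before signature extraction.
#' Both profiles must cover the same gene universe. On linear data, genes
#' with a non-positive class mean cannot be log-ratioed and are excluded
#' (counted in attribute `n_excluded`); with `logged = TRUE` the metric is
#' the difference of means and nothing is excluded.
#'
#' @param treatment,vehicle Gene-level [expression_profile()] objects with
#'   identical row sets.
#' @param logged Set `TRUE` for pre-logged values.
#' @return A [ranked_genes()] object (descending metric), attribute
#'   `n_excluded`.
#' @export
compound_ranked_profile <- function(treatment, vehicle, logged = FALSE) {
  stopifnot(inherits(treatment, "expression_profile"),
            inherits(vehicle, "expression_profile"))
  if (!setequal(rownames(treatment), rownames(vehicle)))
    stop("treatment and vehicle must share the same gene universe")
  v <- unclass(vehicle)[rownames(treatment), , drop = FALSE]
  t_ <- unclass(treatment)
  mT <- rowMeans(t_); mV <- rowMeans(v)
  if (logged) {
    vals <- mT - mV
    keep <- rep(TRUE, length(vals))
  } else {
    keep <- mT > 0 & mV > 0
    vals <- rep(NA_real_, length(mT))
    vals[keep] <- log2(mT[keep] / mV[keep])
  }
  genes <- rownames(t_)[keep]; vals <- vals[keep]
  ord <- order(-vals, genes)
  out <- ranked_genes(genes[ord], vals[ord], metric_name = "log2_ratio_treatment_vs_vehicle")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Extract a fixed-size up/down query signature from a ranked list
#'
#' Takes the first `x` symbols as the up set and the last `x` as the down
#' set (default `x = 50`, the signature size used throughout the compound
#' ranking). The two sets are disjoint because the list must hold at least
#' `2x` genes.
#'
#' @param ranked A [ranked_genes()] object of length >= `2x`.
#' @param x Signature size per side (positive integer, default 50).
#' @param source_id Identifier carried into the signature.
#' @return A [gene_signature()] with `x` up and `x` down genes.
#' @export
extract_signature <- function(ranked, x = 50L, source_id = "query") {
  stopifnot(inherits(ranked, "ranked_genes"))
  x <- as.integer(x)
  if (is.na(x) || x < 1L) stop("x must be a positive integer")
  n <- length(ranked)
  if (n < 2L * x)
    stop(sprintf("size error: ranked list has %d genes but at least %d (2x) are required",
                 n, 2L * x))
  gene_signature(up_genes = ranked$gene_symbols[seq_len(x)],
                 down_genes = ranked$gene_symbols[seq.int(n - x + 1L, n)],
                 source_id = source_id)
}
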