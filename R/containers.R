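#' Construct an expression profile
#'
#' A genes-by-samples (or probes-by-samples) numeric matrix with ordered row
#' and column identifiers, the container behind the GCT reader and the
#' substrate of probe collapsing and differential ranking.
#'
#' @param values Numeric matrix, rows are probes/genes, columns are samples.
#' @param probe_ids Character vector of row identifiers.
#' @param sample_ids Character vector of column identifiers; must be unique.
#' @param descriptions Optional per-probe description text (recycled `""`).
#' @return An object of class `expression_profile`: the matrix with dimnames
#'   set and a `descriptions` attribute.
#' @export
expression_profile <- function(values, probe_ids = rownames(values),
                               sample_ids = colnames(values),
                               descriptions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(probe_ids) || is.null(sample_ids))
    stop("probe_ids and sample_ids are required")
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(probe_ids))
    stop(sprintf("dimension mismatch: %d rows but %d probe ids",
                 nrow(values), length(probe_ids)))
  if (ncol(values) != length(sample_ids))
    stop(sprintf("dimension mismatch: %d columns but %d sample ids",
                 ncol(values), length(sample_ids)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("expression values must be finite")
  if (is.null(descriptions)) descriptions <- rep("", length(probe_ids))
  if (length(descriptions) != length(probe_ids))
    stop("descriptions length must match probe_ids")
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(values, descriptions = as.character(descriptions),
            class = c("expression_profile", "matrix", "array"))
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile: %d probes x %d samples\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a phenotype assignment
#'
#' Two-class (or more) phenotype labels per sample, as read from a CLS file.
#' Downstream differential ranking requires exactly two classes.
#'
#' @param class_labels Ordered character vector of class names (>= 2).
#' @param assignment Integer vector of per-sample class indices (1-based,
#'   into `class_labels`).
#' @return An object of class `phenotype_assignment`.
#' @export
phenotype_assignment <- function(class_labels, assignment) {
  class_labels <- as.character(class_labels)
  assignment <- as.integer(assignment)
  if (length(class_labels) < 2L)
    stop("at least 2 class labels required")
  if (anyDuplicated(class_labels))
    stop("duplicate class labels")
  if (any(assignment < 1L | assignment > length(class_labels)))
    stop("assignment indices out of range")
  structure(list(class_labels = class_labels, assignment = assignment),
            class = "phenotype_assignment")
}

#' @export
print.phenotype_assignment <- function(x, ...) {
  cat(sprintf("phenotype_assignment: %d samples, classes: %s\n",
              length(x$assignment), paste(x$class_labels, collapse = ", ")))
  invisible(x)
}

#' Construct a probe-to-gene-symbol map
#'
#' @param probe_ids Character vector of unique probe identifiers.
#' @param symbols Character vector of non-empty gene symbols (many-to-one
#'   probe-to-symbol is allowed).
#' @param n_dropped Count of input rows dropped for empty/placeholder symbols
#'   (bookkeeping from the CHIP reader).
#' @return Named character vector of class `probe_map` (names are probe ids),
#'   with attribute `n_dropped`.
#' @export
probe_map <- function(probe_ids, symbols, n_dropped = 0L) {
  probe_ids <- as.character(probe_ids)
  symbols <- as.character(symbols)
  if (length(probe_ids) != length(symbols))
    stop("probe_ids and symbols must have equal length")
  if (anyDuplicated(probe_ids))
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  if (any(!nzchar(symbols)))
    stop("empty gene symbols are not allowed in a probe_map")
  structure(stats::setNames(symbols, probe_ids),
            n_dropped = as.integer(n_dropped), class = "probe_map")
}

#' @export
print.probe_map <- function(x, ...) {
  cat(sprintf("probe_map: %d probes -> %d symbols (%d input rows dropped)\n",
              length(x), length(unique(unclass(x))), attr(x, "n_dropped")))
  invisible(x)
}

#' Construct a ranked gene list
#'
#' An ordered list of gene symbols with aligned signed ranking-metric values,
#' position 1 being the most upregulated gene. This is the substrate the
#' weighted Kolmogorov-Smirnov running sum walks over.
#'
#' @param gene_symbols Character vector, no duplicates.
#' @param metric_values Numeric vector aligned with `gene_symbols`, must be
#'   non-increasing.
#' @param metric_name Name of the ranking metric (e.g. `"signal2noise"`,
#'   `"log2_ratio_of_classes"`).
#' @return An object of class `ranked_genes`: a list with elements
#'   `gene_symbols`, `metric_values`, `metric_name`.
#' @export
ranked_genes <- function(gene_symbols, metric_values, metric_name = "metric") {
  gene_symbols <- as.character(gene_symbols)
  metric_values <- as.numeric(metric_values)
  if (length(gene_symbols) != length(metric_values))
    stop("gene_symbols and metric_values must have equal length")
  if (anyDuplicated(gene_symbols))
    stop("duplicate gene symbols in ranked list: ",
         paste(unique(gene_symbols[duplicated(gene_symbols)]), collapse = ", "))
  if (any(!is.finite(metric_values)))
    stop("metric values must be finite")
  if (is.unsorted(rev(metric_values)))
    stop("metric_values must be non-increasing")
  structure(list(gene_symbols = gene_symbols, metric_values = metric_values,
                 metric_name = as.character(metric_name)[1]),
            class = "ranked_genes")
}

#' @export
length.ranked_genes <- function(x) length(x$gene_symbols)

#' @export
print.ranked_genes <- function(x, ...) {
  n <- length(x)
  cat(sprintf("ranked_genes: %d genes, metric '%s' in [%.4g, %.4g]\n",
              n, x$metric_name, x$metric_values[n], x$metric_values[1]))
  invisible(x)
}

#' Construct a compound gene signature
#'
#' Paired sets of a compound instance's most up- and most downregulated
#' genes. When built by [extract_signature()] both sets have size `x`.
#'
#' @param up_genes Character vector of upregulated gene symbols.
#' @param down_genes Character vector of downregulated gene symbols; must be
#'   disjoint from `up_genes`.
#' @param source_id Instance identifier (compound x dose x cell line).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(up_genes, down_genes, source_id = "signature") {
  up_genes <- unique(as.character(up_genes))
  down_genes <- unique(as.character(down_genes))
  overlap <- intersect(up_genes, down_genes)
  if (length(overlap) > 0)
    stop("up and down sets overlap: ", paste(overlap, collapse = ", "))
  structure(list(up_genes = up_genes, down_genes = down_genes,
                 source_id = as.character(source_id)[1]),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up, %d down\n",
              x$source_id, length(x$up_genes), length(x$down_genes)))
  invisible(x)
}
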