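#' Read paired up/down compound signatures from a GMT file
#'
#' GMT stores one gene set per line (`name <tab> description <tab> genes...`).
#' Compound-instance signatures follow the paired-set convention: for each
#' instance `<id>` two sets named `<id>_UP` and `<id>_DN` hold its most up-
#' and downregulated genes. Instances with only one member set are excluded
#' and reported as orphans; duplicate genes within one set are deduplicated
#' with a warning.
#'
#' @param path Path to a GMT file.
#' @return A list of [gene_signature()] objects, one per complete instance,
#'   with attribute `orphans` (character vector of incomplete instance ids).
#' @seealso [write_signatures_gmt()]
#' @export
read_signatures_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("GMT format error: line with fewer than 3 fields: ", substr(ln, 1, 40))
    nm <- f[1]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': %d duplicated gene(s) removed",
                      nm, sum(duplicated(genes))))
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
  }
  nms <- names(sets)
  is_up <- grepl("_UP$", nms)
  is_dn <- grepl("_DN$", nms)
  if (any(!is_up & !is_dn))
    warning("GMT sets without _UP/_DN suffix ignored: ",
            paste(nms[!is_up & !is_dn], collapse = ", "))
  ids_up <- sub("_UP$", "", nms[is_up])
  ids_dn <- sub("_DN$", "", nms[is_dn])
  complete <- intersect(ids_up, ids_dn)
  orphans <- setdiff(union(ids_up, ids_dn), complete)
  if (length(orphans) > 0)
    warning("instances with only one of _UP/_DN excluded: ",
            paste(orphans, collapse = ", "))
  sigs <- lapply(complete, function(id) {
    gene_signature(sets[[paste0(id, "_UP")]], sets[[paste0(id, "_DN")]],
                   source_id = id)
  })
  names(sigs) <- complete
  attr(sigs, "orphans") <- orphans
  sigs
}

#' Write paired up/down signatures to a GMT file
#'
#' @param signatures A list of [gene_signature()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures_gmt <- function(signatures, path) {
  lines <- unlist(lapply(signatures, function(sig) {
    stopifnot(inherits(sig, "gene_signature"))
    c(paste(c(paste0(sig$source_id, "_UP"), "na", sig$up_genes), collapse = "\t"),
      paste(c(paste0(sig$source_id, "_DN"), "na", sig$down_genes), collapse = "\t"))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Export a ranked gene list as a two-column RNK-style TSV
#'
#' @param ranked A [ranked_genes()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_genes"))
  writeLines(paste(ranked$gene_symbols,
                   format(ranked$metric_values, trim = TRUE, digits = 15,
                          scientific = FALSE),
                   sep = "\t"), path)
  invisible(path)
}
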