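# Tabular readers share a strict dialect: UTF-8, tab-delimited, header row,
# no quoted fields.
read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

need_cols <- function(tab, cols, what) {
  miss <- setdiff(cols, names(tab))
  if (length(miss) > 0)
    stop(what, " format error: missing column(s): ", paste(miss, collapse = ", "))
}

#' Read a compound structure table
#'
#' Tab-delimited with columns `compound_id`, `instance_id`, `smiles`,
#' `cell_line`, `therapeutic_flag`. A missing/empty SMILES marks the record
#' structureless (connectivity-only downstream); the therapeutic flag is the
#' approved-drug indicator.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per instance; `structureless` is a
#'   logical column.
#' @export
read_compound_table <- function(path) {
  tab <- read_tsv_strict(path)
  need_cols(tab, c("compound_id", "instance_id", "smiles"), "compound table")
  if (any(is.na(tab$compound_id) | !nzchar(tab$compound_id)))
    stop("compound table: empty compound_id")
  if (is.null(tab$cell_line)) tab$cell_line <- NA_character_
  if (is.null(tab$therapeutic_flag)) tab$therapeutic_flag <- FALSE
  flag <- tab$therapeutic_flag
  tab$therapeutic_flag <- if (is.logical(flag)) flag else
    tolower(as.character(flag)) %in% c("1", "true", "t", "yes", "y")
  tab$smiles <- as.character(tab$smiles)
  tab$structureless <- is.na(tab$smiles) | !nzchar(trimws(tab$smiles))
  tab$instance_id <- as.character(tab$instance_id)
  tab$compound_id <- as.character(tab$compound_id)
  tab
}

# unit factors to nM
.unit_to_nM <- c(nm = 1, nM = 1, "nmol/l" = 1,
                 um = 1e3, uM = 1e3, "µM" = 1e3, "μM" = 1e3,
                 "umol/l" = 1e3,
                 mm = 1e6, mM = 1e6, "mmol/l" = 1e6)

#' Read a bioactivity table (compound-target affinity triples)
#'
#' Tab-delimited with columns `compound_id`, `smiles`, `target_id`,
#' `affinity_nM`, `confidence`. If a `unit` column is present, values are
#' normalized to nM at read time (uM x 1000, mM x 10^6), so all downstream
#' threshold comparisons happen in a single unit. Rows with non-positive
#' affinity, missing fields or an unrecognized unit are rejected and counted.
#'
#' @param path Path to a TSV file.
#' @return A data.frame of accepted triples (affinities in nM) with
#'   attribute `n_rejected` and `rejections` (per-reason counts).
#' @export
read_bioactivities <- function(path) {
  tab <- read_tsv_strict(path)
  need_cols(tab, c("compound_id", "target_id", "affinity_nM", "confidence"),
            "bioactivity")
  if (is.null(tab$smiles)) tab$smiles <- NA_character_
  aff <- suppressWarnings(as.numeric(tab$affinity_nM))
  conf <- suppressWarnings(as.integer(tab$confidence))
  reject_reason <- rep(NA_character_, nrow(tab))
  if (!is.null(tab$unit)) {
    u <- trimws(as.character(tab$unit))
    u[is.na(u) | !nzchar(u)] <- "nM"
    fac <- .unit_to_nM[u]
    reject_reason[is.na(fac)] <- "unknown_unit"
    aff <- aff * unname(fac)
  }
  bad_aff <- is.na(reject_reason) & (is.na(aff) | aff <= 0)
  reject_reason[bad_aff] <- "nonpositive_affinity"
  bad_conf <- is.na(reject_reason) & (is.na(conf) | conf < 0L | conf > 10L)
  reject_reason[bad_conf] <- "invalid_confidence"
  keep <- is.na(reject_reason)
  out <- data.frame(compound_id = as.character(tab$compound_id[keep]),
                    smiles = as.character(tab$smiles[keep]),
                    target_id = as.character(tab$target_id[keep]),
                    affinity_nM = aff[keep],
                    confidence = conf[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- sum(!keep)
  attr(out, "rejections") <- table(reject_reason[!keep])
  out
}

#' Read a disease-gene link table
#'
#' Tab-delimited with gene symbol, disease id and inference-score columns
#' (CTD-style). An empty inference score becomes 0 and the row is flagged;
#' a negative score rejects the row.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `gene_symbol`, `disease_id`,
#'   `inference_score`, `score_imputed`; attribute `n_rejected`.
#' @export
read_disease_links <- function(path) {
  tab <- read_tsv_strict(path)
  gcol <- grep("gene", names(tab), ignore.case = TRUE)[1]
  dcol <- grep("disease", names(tab), ignore.case = TRUE)[1]
  scol <- grep("inference|score", names(tab), ignore.case = TRUE)[1]
  if (is.na(gcol) || is.na(dcol) || is.na(scol))
    stop("disease-link format error: need gene, disease and inference-score columns")
  score <- suppressWarnings(as.numeric(tab[[scol]]))
  imputed <- is.na(score)
  score[imputed] <- 0
  keep <- score >= 0
  out <- data.frame(gene_symbol = as.character(tab[[gcol]][keep]),
                    disease_id = as.character(tab[[dcol]][keep]),
                    inference_score = score[keep],
                    score_imputed = imputed[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Read a gene-to-protein mapping table
#'
#' Tab-delimited with columns `target_id` and `gene_symbol`, linking protein
#' target identifiers to the gene symbols used in disease-link tables.
#'
#' @param path Path to a TSV file.
#' @return A named character vector mapping `target_id` to `gene_symbol`.
#' @export
read_gene_protein_map <- function(path) {
  tab <- read_tsv_strict(path)
  need_cols(tab, c("target_id", "gene_symbol"), "gene-protein map")
  keep <- !is.na(tab$gene_symbol) & nzchar(tab$gene_symbol)
  stats::setNames(as.character(tab$gene_symbol[keep]),
                  as.character(tab$target_id[keep]))
}

#' Write a data.frame as an unquoted TSV
#'
#' @param tab A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
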