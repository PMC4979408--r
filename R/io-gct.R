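#' Read a GCT v1.2 expression matrix
#'
#' GCT is the Broad Institute's tab-delimited expression format: a `#1.2`
#' version tag, a line with the row and column counts, a header line
#' (`NAME`, `Description`, sample ids), then one row per probe. Only v1.2 is
#' supported; v1.3 files (extra metadata rows) are rejected explicitly.
#'
#' @param path Path to a GCT file.
#' @return An [expression_profile()] whose dimensions equal the declared
#'   counts and whose column order matches the file exactly.
#' @seealso [write_gct()]
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("GCT format error: fewer than 3 lines")
  tag <- trimws(lines[1])
  if (tag == "#1.3")
    stop("GCT format error: version '#1.3' is not supported, only '#1.2'")
  if (tag != "#1.2")
    stop("GCT format error: first line must be the version tag '#1.2', found '",
         tag, "'")
  dims <- strsplit(trimws(lines[2]), "\t| +")[[1]]
  dims <- suppressWarnings(as.integer(dims[nzchar(dims)]))
  if (length(dims) < 2L || any(is.na(dims[1:2])))
    stop("GCT format error: second line must give row and column counts")
  n_rows <- dims[1]; n_cols <- dims[2]
  header <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  if (length(header) != n_cols + 2L)
    stop(sprintf(
      "GCT dimension error: header declares %d columns, expected %d samples + 2",
      length(header), n_cols))
  sample_ids <- header[-(1:2)]
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != n_rows)
    stop(sprintf("GCT dimension error: expected=%d data rows, found=%d",
                 n_rows, length(body)))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != n_cols + 2L))
    stop(sprintf("GCT dimension error: row %d has %d fields, expected %d",
                 which(nf != n_cols + 2L)[1], nf[nf != n_cols + 2L][1],
                 n_cols + 2L))
  probe_ids <- vapply(fields, `[`, character(1), 1L)
  descriptions <- vapply(fields, `[`, character(1), 2L)
  values <- matrix(NA_real_, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    v <- suppressWarnings(as.numeric(fields[[i]][-(1:2)]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("GCT parse error: non-numeric value at data row %d, sample column %d ('%s')",
                   i, j, fields[[i]][j + 2L]))
    }
    values[i, ] <- v
  }
  expression_profile(values, probe_ids, sample_ids, descriptions)
}

#' Write a GCT v1.2 file
#'
#' @param profile An [expression_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  desc <- attr(profile, "descriptions")
  m <- unclass(profile)
  lines <- c(
    "#1.2",
    paste(nrow(m), ncol(m), sep = "\t"),
    paste(c("NAME", "Description", colnames(m)), collapse = "\t"),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(rownames(m)[i], desc[i],
              format(m[i, ], trim = TRUE, digits = 15, scientific = FALSE)),
            collapse = "\t")
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CLS phenotype file
#'
#' Space-delimited categorical CLS: a `N k 1` header line, a `#`-prefixed
#' class-label line, and an assignment line. The assignment line may use
#' 0-based class indices (ordered as on the label line) or the class names
#' themselves; both resolve identically.
#'
#' @param path Path to a CLS file.
#' @return A [phenotype_assignment()] aligned positionally to the GCT
#'   column order.
#' @export
read_cls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS format error: fewer than 3 lines")
  tok <- function(s) { x <- strsplit(trimws(s), "[ \t]+")[[1]]; x[nzchar(x)] }
  hdr <- suppressWarnings(as.integer(tok(lines[1])))
  if (length(hdr) != 3L || anyNA(hdr))
    stop("CLS format error: header must be three integers 'N k 1'")
  n_samples <- hdr[1]; n_classes <- hdr[2]
  lab <- tok(lines[2])
  if (lab[1] != "#")
    stop("CLS format error: second line must start with '#'")
  class_labels <- lab[-1]
  if (length(class_labels) != n_classes)
    stop(sprintf("CLS format error: header declares %d classes, label line has %d",
                 n_classes, length(class_labels)))
  a <- tok(lines[3])
  if (length(a) != n_samples)
    stop(sprintf("CLS format error: header declares %d samples, assignment line has %d tokens",
                 n_samples, length(a)))
  if (all(a %in% class_labels)) {
    idx <- match(a, class_labels)
  } else {
    ia <- suppressWarnings(as.integer(a))
    if (anyNA(ia))
      stop("CLS format error: assignment tokens are neither class names nor integers")
    # CLS indices are 0-based in the order classes first appear on line 3,
    # which by convention matches the label-line order
    if (any(ia < 0L | ia >= n_classes))
      stop("CLS format error: class index out of range")
    idx <- ia + 1L
  }
  phenotype_assignment(class_labels, idx)
}

#' Write a CLS phenotype file
#'
#' @param phen A [phenotype_assignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cls <- function(phen, path) {
  stopifnot(inherits(phen, "phenotype_assignment"))
  lines <- c(
    paste(length(phen$assignment), length(phen$class_labels), 1),
    paste(c("#", phen$class_labels), collapse = " "),
    paste(phen$assignment - 1L, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a CHIP probe-to-symbol translation file
#'
#' Tab-delimited with a header containing `Probe Set ID` and `Gene Symbol`
#' columns. Rows with an empty or placeholder (`---`, `NA`) symbol are
#' dropped and counted. A probe id appearing twice with the same symbol is
#' accepted; with conflicting symbols it is an error.
#'
#' @param path Path to a CHIP file.
#' @return A [probe_map()] with attribute `n_dropped`.
#' @export
read_chip <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE, check.names = FALSE)
  pcol <- grep("probe", names(tab), ignore.case = TRUE)[1]
  scol <- grep("symbol", names(tab), ignore.case = TRUE)[1]
  if (is.na(pcol) || is.na(scol))
    stop("CHIP format error: header must contain probe-id and gene-symbol columns")
  probes <- trimws(as.character(tab[[pcol]]))
  symbols <- trimws(as.character(tab[[scol]]))
  placeholder <- is.na(symbols) | !nzchar(symbols) | symbols %in% c("---", "NA", "null")
  n_dropped <- sum(placeholder)
  probes <- probes[!placeholder]; symbols <- symbols[!placeholder]
  if (anyDuplicated(probes)) {
    pair <- !duplicated(paste0(probes, "\r", symbols))
    probes <- probes[pair]; symbols <- symbols[pair]
    if (anyDuplicated(probes)) {
      bad <- unique(probes[duplicated(probes)])
      stop("CHIP conflict error: probe(s) mapped to different symbols: ",
           paste(bad, collapse = ", "))
    }
  }
  probe_map(probes, symbols, n_dropped = n_dropped)
}

#' Write a CHIP file
#'
#' @param map A [probe_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chip <- function(map, path) {
  stopifnot(inherits(map, "probe_map"))
  lines <- c("Probe Set ID\tGene Symbol",
             paste(names(map), unclass(map), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
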