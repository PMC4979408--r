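#' Filter bioactivity triples to the training set
#'
#' Keeps a compound-target pair for training iff its binding affinity is
#' strictly below 10 uM (10000 nM, affinities already unit-normalized by
#' [read_bioactivities()]) and the assay confidence level is 9 or 10. A
#' record at exactly 10 uM is rejected (strict inequality). Activity is an
#' existence criterion across assays: a pair is active if any of its assays
#' passes.
#'
#' @param triples Data.frame from [read_bioactivities()] (columns
#'   `compound_id`, `target_id`, `affinity_nM`, `confidence`).
#' @param affinity_max_nM Threshold in nM (default 10000, i.e. 10 uM).
#' @param confidence_levels Accepted confidence levels (default 9 and 10).
#' @return The retained subset (a data.frame), with attribute `rejections`,
#'   a named vector counting rejected rows by reason (`affinity`,
#'   `confidence`, `both`).
#' @export
filter_bioactivities <- function(triples, affinity_max_nM = 10000,
                                 confidence_levels = c(9L, 10L)) {
  ok_aff <- triples$affinity_nM < affinity_max_nM
  ok_conf <- triples$confidence %in% confidence_levels
  keep <- ok_aff & ok_conf
  out <- triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- c(
    affinity = sum(!ok_aff & ok_conf),
    confidence = sum(ok_aff & !ok_conf),
    both = sum(!ok_aff & !ok_conf))
  out
}

#' Train Laplacian-modified naive Bayes target models
#'
#' Builds one model per protein target from filtered bioactivity triples and
#' per-compound fingerprints. For each target t the model stores the number
#' of unique active compounds `n_actives` and per-feature active counts
#' `A_tf`; globally it stores the training-set size `n_total` (unique
#' compounds) and per-feature totals `T_f`. The target prior is
#' P(t) = n_actives / n_total. Duplicate compound-target pairs are
#' deduplicated, so repeated assay rows never inflate the counts.
#'
#' @param triples Filtered bioactivity data.frame ([filter_bioactivities()]).
#' @param fingerprints Named list mapping compound_id to an integer vector
#'   of fingerprint feature ids ([fingerprint_ecfp4()] output, or abstract
#'   feature sets).
#' @return An object of class `target_models`: list with `targets` (named
#'   list per target: `n_actives`, `a_tf` named count vector), `t_f` (global
#'   named feature counts), `n_total`.
#' @export
train_target_models <- function(triples, fingerprints) {
  if (nrow(triples) < 1L) stop("no triples left after filtering")
  pairs <- unique(triples[, c("compound_id", "target_id")])
  compounds <- unique(pairs$compound_id)
  have_fp <- compounds %in% names(fingerprints) &
    !vapply(fingerprints[compounds], is.null, logical(1))
  if (any(!have_fp))
    stop("missing fingerprints for compound(s): ",
         paste(utils::head(compounds[!have_fp], 5), collapse = ", "))
  feat_count <- function(ids) {
    f <- unlist(lapply(fingerprints[ids], unique), use.names = FALSE)
    if (length(f) == 0) return(stats::setNames(integer(0), character(0)))
    tab <- table(f)
    stats::setNames(as.integer(tab), names(tab))
  }
  t_f <- feat_count(compounds)
  n_total <- length(compounds)
  split_pairs <- split(pairs$compound_id, pairs$target_id)
  targets <- lapply(split_pairs, function(ids) {
    ids <- unique(ids)
    list(n_actives = length(ids), a_tf = feat_count(ids))
  })
  empty <- vapply(targets, function(t) t$n_actives < 1L, logical(1))
  if (any(empty)) {
    warning("target(s) with zero surviving actives omitted: ",
            paste(names(targets)[empty], collapse = ", "))
    targets <- targets[!empty]
  }
  structure(list(targets = targets, t_f = t_f, n_total = n_total),
            class = "target_models")
}

#' @export
print.target_models <- function(x, ...) {
  cat(sprintf("target_models: %d targets, %d training compounds, %d features\n",
              length(x$targets), x$n_total, length(x$t_f)))
  invisible(x)
}

#' Score a compound's fingerprint against all target models
#'
#' The Laplacian-modified naive Bayes score of target t for a fingerprint is
#' the sum over its features f of log[(A_tf + 1) / (T_f * P(t) + 1)], where
#' A_tf is the feature's count among the target's actives, T_f its count in
#' the whole training set and P(t) the target prior. The Laplacian
#' correction makes features unseen in training contribute
#' log((0+1)/(0+1)) = 0, i.e. they are neutral. Targets are returned sorted
#' by score (descending), truncated to `top_k`.
#'
#' @param fp Integer vector of fingerprint feature ids (may be empty or
#'   `NULL` for a structureless compound: all scores 0, flagged).
#' @param models A `target_models` object from [train_target_models()].
#' @param top_k Number of top targets to return (default 5); `Inf` for all.
#' @param compound_id Identifier copied into the result.
#' @return Data.frame with columns `compound_id`, `target_id`, `score`,
#'   `rank` (1..k without gaps); attribute `empty_fingerprint` flags the
#'   structureless case.
#' @export
score_targets <- function(fp, models, top_k = 5L, compound_id = NA_character_) {
  stopifnot(inherits(models, "target_models"))
  empty <- is.null(fp) || length(fp) == 0L
  tnames <- names(models$targets)
  if (empty) {
    scores <- stats::setNames(rep(0, length(tnames)), tnames)
  } else {
    f <- as.character(unique(fp))
    t_f <- models$t_f[f]
    t_f[is.na(t_f)] <- 0
    scores <- vapply(models$targets, function(t) {
      a <- t$a_tf[f]
      a[is.na(a)] <- 0
      p_t <- t$n_actives / models$n_total
      sum(log((a + 1) / (t_f * p_t + 1)))
    }, numeric(1))
  }
  ord <- order(-scores, tnames)
  k <- min(length(scores), top_k)
  out <- data.frame(compound_id = compound_id,
                    target_id = tnames[ord][seq_len(k)],
                    score = unname(scores[ord])[seq_len(k)],
                    rank = seq_len(k),
                    stringsAsFactors = FALSE)
  attr(out, "empty_fingerprint") <- empty
  out
}

#' Predict targets for a batch of compounds
#'
#' @param fingerprints Named list of feature-id vectors (compound_id keyed;
#'   `NULL` entries are structureless and yield all-zero scores).
#' @inheritParams score_targets
#' @return One data.frame stacking [score_targets()] results for every
#'   compound.
#' @export
predict_targets <- function(fingerprints, models, top_k = 5L) {
  out <- do.call(rbind, lapply(names(fingerprints), function(id)
    score_targets(fingerprints[[id]], models, top_k, compound_id = id)))
  rownames(out) <- NULL
  out
}

#' Annotate predictions with direct experimental support
#'
#' Predictions whose compound-target pair has a measured bioactivity carry
#' `experimental_support_nM`, the minimum affinity across that pair's assays
#' (e.g. a prediction confirmed by a measured IC50); unsupported pairs get
#' `NA`.
#'
#' @param predictions Data.frame from [predict_targets()].
#' @param measured Bioactivity data.frame (unit-normalized nM).
#' @return `predictions` with the `experimental_support_nM` column added.
#' @export
flag_known_targets <- function(predictions, measured) {
  key <- paste(predictions$compound_id, predictions$target_id, sep = "\r")
  mkey <- paste(measured$compound_id, measured$target_id, sep = "\r")
  best <- tapply(measured$affinity_nM, mkey, min)
  predictions$experimental_support_nM <- as.numeric(best[key])
  predictions
}

#' Serialize target models to a versioned TSV bundle
#'
#' Plain-text persistence: a header section with the format version,
#' training-set size and per-target priors, then sparse count rows
#' (`target_id`, `feature_id`, `count`), with the global feature totals
#' stored under the pseudo-target `__total__`.
#'
#' @param models A `target_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_models <- function(models, path) {
  stopifnot(inherits(models, "target_models"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#cmselect_target_models\tv1",
               paste0("#n_total\t", models$n_total)), con)
  writeLines(vapply(names(models$targets), function(tn)
    paste0("#target\t", tn, "\t", models$targets[[tn]]$n_actives),
    character(1)), con)
  writeLines("target_id\tfeature_id\tcount", con)
  for (tn in names(models$targets)) {
    a <- models$targets[[tn]]$a_tf
    if (length(a) > 0)
      writeLines(paste(tn, names(a), a, sep = "\t"), con)
  }
  tf <- models$t_f
  if (length(tf) > 0)
    writeLines(paste("__total__", names(tf), tf, sep = "\t"), con)
  invisible(path)
}

#' Read a target-model TSV bundle
#'
#' @param path Path written by [write_target_models()].
#' @return A `target_models` object.
#' @export
read_target_models <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "#cmselect_target_models"))
    stop("not a target-model bundle: ", path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  n_total <- as.integer(strsplit(grep("^#n_total", meta, value = TRUE),
                                 "\t")[[1]][2])
  tmeta <- strsplit(grep("^#target\t", meta, value = TRUE), "\t")
  n_act <- stats::setNames(
    vapply(tmeta, function(x) as.integer(x[3]), integer(1)),
    vapply(tmeta, function(x) x[2], character(1)))
  body <- body[-1]  # header row
  f <- strsplit(body, "\t", fixed = TRUE)
  tid <- vapply(f, `[`, character(1), 1)
  fid <- vapply(f, `[`, character(1), 2)
  cnt <- as.integer(vapply(f, `[`, character(1), 3))
  is_tot <- tid == "__total__"
  t_f <- stats::setNames(cnt[is_tot], fid[is_tot])
  targets <- lapply(names(n_act), function(tn) {
    sel <- tid == tn
    list(n_actives = unname(n_act[tn]),
         a_tf = stats::setNames(cnt[sel], fid[sel]))
  })
  names(targets) <- names(n_act)
  structure(list(targets = targets, t_f = t_f, n_total = n_total),
            class = "target_models")
}
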