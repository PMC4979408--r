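#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks down a ranked gene list keeping a running sum: at each query-set
#' gene ("hit") the sum increases by that gene's weight, at every other gene
#' it decreases by a constant. With weight exponent `p = 1` (default) the
#' hit weight at position i is |metric_i|^p / N_R where
#' N_R = sum over hits of |metric|^p, so hits near the extremes of the list
#' count more — the weighted Kolmogorov-Smirnov statistic; `p = 0` gives the
#' classic unweighted KS statistic (each hit contributes 1 / n_hits) used by
#' the original Connectivity Map. Misses subtract 1 / (N - n_hits). The
#' enrichment score is the signed value of the running sum at its maximum
#' absolute deviation from zero (earliest position on ties), and always lies
#' in [-1, 1]: +1 when the query occupies the very top of the list, -1 when
#' it occupies the very bottom, near 0 for an uncorrelated query.
#'
#' Query genes absent from the ranked list are dropped and counted in
#' `hits_missing`; an error is raised only when no query gene is present, or
#' when the query covers the whole list (no misses, degenerate walk). If
#' `p = 1` and every hit has metric exactly 0 (so N_R = 0), hit weights fall
#' back to the uniform `p = 0` form to keep the score defined.
#'
#' @param ranked A [ranked_genes()] object.
#' @param query Character vector of query gene symbols.
#' @param p Weight exponent, 0 or 1 (default 1).
#' @return An object of class `enrichment_result`: list with `es`,
#'   `peak_position`, `hits_found`, `hits_missing`, `hit_positions`.
#' @references Subramanian et al. (2005) PNAS 102:15545; Lamb et al. (2006)
#'   Science 313:1929.
#' @export
enrichment_score <- function(ranked, query, p = 1) {
  stopifnot(inherits(ranked, "ranked_genes"))
  if (!p %in% c(0, 1)) stop("weight exponent p must be 0 or 1")
  query <- unique(as.character(query))
  n <- length(ranked)
  if (n == 0L) stop("ranked list is empty")
  pos <- match(query, ranked$gene_symbols)
  hits_missing <- sum(is.na(pos))
  pos <- sort(pos[!is.na(pos)])
  n_hits <- length(pos)
  if (n_hits == 0L)
    stop("empty-overlap error: no query gene is present in the ranked list")
  if (n_hits >= n)
    stop("degenerate error: query covers the entire ranked list (no misses)")
  w <- if (p == 0) rep(1, n_hits) else abs(ranked$metric_values[pos])
  n_r <- sum(w)
  if (n_r == 0) { w <- rep(1, n_hits); n_r <- n_hits }  # all-zero-metric hits
  step <- rep(-1 / (n - n_hits), n)
  step[pos] <- w / n_r
  run <- cumsum(step)
  # earliest position attaining the maximal |deviation|; the small tolerance
  # keeps the tie-break stable under floating-point accumulation order
  peak <- which(abs(run) >= max(abs(run)) - 1e-9)[1]
  structure(list(es = run[peak], peak_position = peak,
                 hits_found = n_hits, hits_missing = hits_missing,
                 hit_positions = pos),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: es = %.4f (peak at %d; %d hits, %d missing)\n",
              x$es, x$peak_position, x$hits_found, x$hits_missing))
  invisible(x)
}

#' Leading-edge genes of an enrichment
#'
#' The query genes that drive the enrichment signal: for a non-negative
#' enrichment score, the query genes at or before the running-sum peak; for
#' a negative score, those at or after it. Returned in ranked-list order.
#'
#' @inheritParams enrichment_score
#' @return Character vector of leading-edge gene symbols.
#' @export
leading_edge <- function(ranked, query, p = 1) {
  er <- enrichment_score(ranked, query, p)
  pos <- if (er$es >= 0) er$hit_positions[er$hit_positions <= er$peak_position]
         else er$hit_positions[er$hit_positions >= er$peak_position]
  ranked$gene_symbols[pos]
}

#' Connectivity of a compound signature with a tissue profile
#'
#' Scores one compound instance against the ranked tissue differential
#' profile: the up set and the down set each get an enrichment score
#' (`score_up`, `score_down`), combined as
#' `combined = (score_up - score_down) / 2`. A positive combined score
#' means the instance mimics the profile (its upregulated genes sit at the
#' profile's top and its downregulated genes at the bottom); a negative
#' score means it reverses it. No same-sign zeroing is applied — the
#' combined score is always the formula value; `sign_agreement` flags
#' signature pairs whose two scores share a sign, for which the mimic /
#' reverse reading is weaker.
#'
#' @param tissue_ranked A [ranked_genes()] tissue profile.
#' @param sig A [gene_signature()].
#' @param p Weight exponent passed to [enrichment_score()].
#' @return An object of class `connectivity_result`: list with `source_id`,
#'   `score_up`, `score_down`, `combined`, `sign_agreement`,
#'   `n_hits_up`, `n_hits_down`, `leading_edge_up`, `leading_edge_down`.
#' @export
connectivity <- function(tissue_ranked, sig, p = 1) {
  stopifnot(inherits(sig, "gene_signature"))
  er_up <- tryCatch(enrichment_score(tissue_ranked, sig$up_genes, p),
                    error = function(e)
                      stop("up set of '", sig$source_id, "': ",
                           conditionMessage(e), call. = FALSE))
  er_dn <- tryCatch(enrichment_score(tissue_ranked, sig$down_genes, p),
                    error = function(e)
                      stop("down set of '", sig$source_id, "': ",
                           conditionMessage(e), call. = FALSE))
  le <- function(er) {
    pos <- if (er$es >= 0) er$hit_positions[er$hit_positions <= er$peak_position]
           else er$hit_positions[er$hit_positions >= er$peak_position]
    tissue_ranked$gene_symbols[pos]
  }
  structure(list(source_id = sig$source_id,
                 score_up = er_up$es, score_down = er_dn$es,
                 combined = (er_up$es - er_dn$es) / 2,
                 sign_agreement = sign(er_up$es) == sign(er_dn$es) &&
                   er_up$es != 0,
                 n_hits_up = er_up$hits_found, n_hits_down = er_dn$hits_found,
                 leading_edge_up = le(er_up), leading_edge_down = le(er_dn)),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("connectivity '%s': up %.4f, down %.4f, combined %.4f\n",
              x$source_id, x$score_up, x$score_down, x$combined))
  invisible(x)
}

#' Rank scored compound instances
#'
#' Sorts connectivity results into the rank-ordered candidate list:
#' `rank_positive` 1 is the strongest mimic (largest combined score) and
#' `rank_negative` 1 the strongest reverser (smallest). Tied scores share
#' consecutive ranks in `source_id` order, consistently in both directions.
#'
#' @param results A list of `connectivity_result` objects (or a data.frame
#'   already holding `source_id` and `combined`).
#' @param per_compound Optional named vector mapping `source_id` (instance)
#'   to compound id; when supplied, an extra aggregation keeps each
#'   compound's extreme combined score (off by default — ranking granularity
#'   is the instance).
#' @return A data.frame ordered by `rank_positive` with columns `source_id`,
#'   `score_up`, `score_down`, `combined`, `sign_agreement`, `n_hits_up`,
#'   `n_hits_down`, `rank_positive`, `rank_negative`, `leading_edge_up`,
#'   `leading_edge_down` (the last two semicolon-joined).
#' @export
rank_instances <- function(results, per_compound = NULL) {
  if (is.data.frame(results)) {
    tab <- results
    if (!all(c("source_id", "combined") %in% names(tab)))
      stop("data.frame input needs source_id and combined columns")
  } else {
    if (length(results) < 1L) stop("at least one connectivity result required")
    tab <- do.call(rbind, lapply(results, function(r) {
      stopifnot(inherits(r, "connectivity_result"))
      data.frame(source_id = r$source_id, score_up = r$score_up,
                 score_down = r$score_down, combined = r$combined,
                 sign_agreement = r$sign_agreement,
                 n_hits_up = r$n_hits_up, n_hits_down = r$n_hits_down,
                 leading_edge_up = paste(r$leading_edge_up, collapse = ";"),
                 leading_edge_down = paste(r$leading_edge_down, collapse = ";"),
                 stringsAsFactors = FALSE)
    }))
  }
  n <- nrow(tab)
  ord_pos <- order(-tab$combined, tab$source_id)
  ord_neg <- order(tab$combined, tab$source_id)
  tab$rank_positive <- NA_integer_
  tab$rank_negative <- NA_integer_
  tab$rank_positive[ord_pos] <- seq_len(n)
  tab$rank_negative[ord_neg] <- seq_len(n)
  tab <- tab[ord_pos, , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(per_compound)) {
    cid <- per_compound[tab$source_id]
    if (anyNA(cid)) stop("per_compound does not cover all source ids")
    extreme <- vapply(split(tab$combined, cid), function(v)
      v[which.max(abs(v))], numeric(1))
    attr(tab, "compound_extreme") <-
      sort(extreme, decreasing = TRUE)
  }
  tab
}

#' Score a cohort of signatures and rank them
#'
#' Convenience wrapper: runs [connectivity()] for every signature and feeds
#' the results through [rank_instances()].
#'
#' @param tissue_ranked A [ranked_genes()] tissue profile.
#' @param signatures List of [gene_signature()] objects.
#' @inheritParams rank_instances
#' @param p Weight exponent.
#' @return The ranked data.frame from [rank_instances()].
#' @export
connectivity_rank <- function(tissue_ranked, signatures, p = 1,
                              per_compound = NULL) {
  rank_instances(lapply(signatures, function(s)
    connectivity(tissue_ranked, s, p)), per_compound = per_compound)
}

#' Empirical null distribution of the enrichment score
#'
#' Enrichment scores of `n_perm` query sets of size `set_size` drawn
#' uniformly at random from the ranked list — the expected behaviour of an
#' uncorrelated signature, centred on zero. Deterministic for a fixed seed.
#'
#' @param ranked A [ranked_genes()] object.
#' @param set_size Query size, must be < length(ranked).
#' @param n_perm Number of random sets (>= 1).
#' @param seed Integer RNG seed.
#' @param p Weight exponent.
#' @return Numeric vector of `n_perm` enrichment scores.
#' @export
null_distribution <- function(ranked, set_size, n_perm, seed = 1L, p = 1) {
  stopifnot(inherits(ranked, "ranked_genes"))
  n <- length(ranked)
  if (set_size >= n) stop("set_size must be smaller than the ranked list")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    q <- sample(ranked$gene_symbols, set_size)
    enrichment_score(ranked, q, p)$es
  }, numeric(1))
}
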