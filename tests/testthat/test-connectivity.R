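test_that("query at the top of the list gives es = 1, at the bottom -1", {
  ranked <- random_ranked(200, seed = 1)
  top20 <- ranked$gene_symbols[1:20]
  bottom20 <- ranked$gene_symbols[181:200]
  for (p in c(0, 1)) {
    expect_equal(enrichment_score(ranked, top20, p = p)$es, 1)
    expect_equal(enrichment_score(ranked, bottom20, p = p)$es, -1)
  }
})

test_that("hand-stepped running sum on a 5-gene list matches", {
  ranked <- ranked_genes(paste0("gene", 1:5), c(3, 2, 1, -1, -2))
  # query = {gene2, gene5}, p = 1: N_R = |2| + |-2| = 4, miss step = -1/3
  # running sum: -1/3, -1/3 + 2/4 = 1/6, 1/6 - 1/3 = -1/6, -1/6 - 1/3 = -1/2,
  # -1/2 + 2/4 = 0 -> extreme |deviation| = 1/2 at position 4, es = -1/2
  er <- enrichment_score(ranked, c("gene2", "gene5"), p = 1)
  expect_equal(er$es, -0.5, tolerance = 1e-15)
  expect_equal(er$peak_position, 4L)
  expect_equal(er$hits_found, 2L)
  # and the naive O(N^2) oracle agrees
  expect_equal(er$es, oracle_es(paste0("gene", 1:5), c(3, 2, 1, -1, -2),
                                c("gene2", "gene5")), tolerance = 1e-15)
})

test_that("streaming implementation equals the O(N^2) oracle on random instances", {
  set.seed(2024)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    ranked <- random_ranked(n)
    k <- sample(1:(n - 1), 1)
    query <- sample(ranked$gene_symbols, k)
    p <- sample(c(0, 1), 1)
    er <- enrichment_score(ranked, query, p = p)
    expect_equal(er$es, oracle_es(ranked$gene_symbols, ranked$metric_values,
                                  query, p = p),
                 tolerance = 1e-12)
    expect_gte(er$es, -1)
    expect_lte(er$es, 1)
  }
})

test_that("weighted scores agree with an established GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  for (i in 1:50) {
    n <- sample(50:200, 1)
    ranked <- random_ranked(n)
    query <- sample(ranked$gene_symbols, sample(5:25, 1))
    stats_vec <- stats::setNames(ranked$metric_values, ranked$gene_symbols)
    ref <- fgsea::calcGseaStat(stats_vec,
                               selectedStats = match(query, names(stats_vec)),
                               gseaParam = 1)
    expect_equal(enrichment_score(ranked, query, p = 1)$es, ref,
                 tolerance = 1e-10)
  }
})

test_that("absent query genes are dropped and counted; degenerate queries error", {
  ranked <- random_ranked(30, seed = 3)
  query <- c(ranked$gene_symbols[1:5], "NOT_A_GENE", "ALSO_MISSING")
  er <- enrichment_score(ranked, query)
  expect_equal(er$hits_found, 5L)
  expect_equal(er$hits_missing, 2L)
  expect_equal(er$hits_found + er$hits_missing, 7L)
  expect_error(enrichment_score(ranked, c("x", "y")), "empty-overlap")
  expect_error(enrichment_score(ranked, ranked$gene_symbols), "degenerate")
})

test_that("all-zero-metric hits fall back to uniform weights, not NaN", {
  ranked <- ranked_genes(paste0("g", 1:6), c(2, 1, 0, 0, -1, -2))
  er <- enrichment_score(ranked, c("g3", "g4"), p = 1)
  expect_true(is.finite(er$es))
  expect_equal(er$es, oracle_es(paste0("g", 1:6), c(2, 1, 0, 0, -1, -2),
                                c("g3", "g4")), tolerance = 1e-15)
})

test_that("combined score follows the half-difference formula", {
  ranked <- random_ranked(500, seed = 4)
  sig <- gene_signature(ranked$gene_symbols[1:50],
                        ranked$gene_symbols[451:500], "mimic")
  res <- connectivity(ranked, sig)
  expect_equal(res$score_up, 1)
  expect_equal(res$score_down, -1)
  expect_equal(res$combined, 1)   # (1 - (-1)) / 2
  expect_equal(res$combined, (res$score_up - res$score_down) / 2)
})

test_that("swapping up and down sets negates the combined score exactly", {
  set.seed(6)
  ranked <- random_ranked(400)
  for (i in 1:100) {
    pick <- sample(ranked$gene_symbols, 60)
    sig <- gene_signature(pick[1:30], pick[31:60], "s")
    swapped <- gene_signature(pick[31:60], pick[1:30], "s")
    a <- connectivity(ranked, sig)
    b <- connectivity(ranked, swapped)
    expect_equal(b$combined, -a$combined, tolerance = 1e-15)
    expect_equal(a$combined, (a$score_up - a$score_down) / 2, tolerance = 1e-15)
  }
})

test_that("connectivity names the failing signature side in errors", {
  ranked <- random_ranked(50, seed = 8)
  sig <- gene_signature(c("nope1", "nope2"), ranked$gene_symbols[1:5], "bad")
  expect_error(connectivity(ranked, sig), "up set of 'bad'")
})

test_that("rank_instances assigns both rank directions with source_id tie-break", {
  mk <- function(id, comb) structure(
    list(source_id = id, score_up = comb, score_down = -comb, combined = comb,
         sign_agreement = FALSE, n_hits_up = 1L, n_hits_down = 1L,
         leading_edge_up = character(0), leading_edge_down = character(0)),
    class = "connectivity_result")
  tab <- rank_instances(list(mk("a", 0.9), mk("b", -0.9), mk("c", 0.1)))
  got <- tab[order(tab$source_id), ]
  expect_equal(got$rank_positive, c(1L, 3L, 2L))
  expect_equal(got$rank_negative, c(3L, 1L, 2L))

  ties <- rank_instances(list(mk("z", 0.5), mk("a", 0.5), mk("m", 0.5)))
  expect_equal(ties$source_id, c("a", "m", "z"))  # id-ascending on ties
  expect_equal(ties$rank_positive, 1:3)
  expect_equal(ties$rank_negative, 1:3)
})

test_that("per-compound aggregation keeps each compound's extreme score", {
  mk <- function(id, comb) structure(
    list(source_id = id, score_up = comb, score_down = -comb, combined = comb,
         sign_agreement = FALSE, n_hits_up = 1L, n_hits_down = 1L,
         leading_edge_up = character(0), leading_edge_down = character(0)),
    class = "connectivity_result")
  tab <- rank_instances(list(mk("i1", 0.2), mk("i2", -0.8), mk("i3", 0.5)),
                        per_compound = c(i1 = "drugA", i2 = "drugA",
                                         i3 = "drugB"))
  ext <- attr(tab, "compound_extreme")
  expect_equal(unname(ext["drugA"]), -0.8)   # extreme by |combined|
  expect_equal(unname(ext["drugB"]), 0.5)
})

test_that("leading edge returns the hits before (or after) the peak", {
  ranked <- random_ranked(100, seed = 9)
  top <- ranked$gene_symbols[1:10]
  expect_setequal(leading_edge(ranked, top), top)  # all hits precede the peak
  one <- ranked$gene_symbols[37]
  expect_equal(leading_edge(ranked, one), one)
})

test_that("a planted 12-gene overlap is recovered exactly as the leading edge", {
  # 500-gene profile; the query holds 12 genes inside the top 30 (the planted
  # overlap, driving the peak) and 8 genes scattered well below it
  set.seed(10)
  ranked <- random_ranked(500)
  planted <- ranked$gene_symbols[seq(2, 24, by = 2)]     # 12 genes near the top
  stragglers <- ranked$gene_symbols[seq(300, 440, by = 20)]  # 8 deep genes
  query <- c(planted, stragglers)
  er <- enrichment_score(ranked, query)
  expect_gt(er$es, 0)
  le <- leading_edge(ranked, query)
  expect_identical(sort(le), sort(planted))
})

test_that("null distribution is seed-deterministic, bounded and centred", {
  # antisymmetric metric grid: the null is exactly symmetric about zero
  ranked <- symmetric_ranked(1000, seed = 11)
  a <- null_distribution(ranked, set_size = 50, n_perm = 200, seed = 123)
  b <- null_distribution(ranked, set_size = 50, n_perm = 200, seed = 123)
  expect_identical(a, b)
  expect_true(all(a >= -1 & a <= 1))
  se <- sd(a) / sqrt(length(a))
  expect_lt(abs(mean(a)), 3 * se)
  expect_error(null_distribution(ranked, set_size = 1000, n_perm = 1),
               "smaller")
})

test_that("a planted strong mimic attains rank_positive 1 in a large cohort", {
  # cohort cardinality mirrors an instance-level screen; one instance's
  # signature is drawn from the profile's extreme deciles
  set.seed(12)
  ranked <- random_ranked(2000)
  spec <- fixture_spec(seed = 12, n_instances = 300, n_planted_mimics = 1,
                       n_planted_reversers = 1)
  inst <- gen_compound_instances(spec, ranked)
  tab <- connectivity_rank(ranked, inst$signatures)
  mimic <- inst$truth$source_id[inst$truth$role == "mimic"]
  reverser <- inst$truth$source_id[inst$truth$role == "reverser"]
  expect_equal(tab$source_id[tab$rank_positive == 1L], mimic)
  expect_equal(tab$source_id[tab$rank_negative == 1L], reverser)
})
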