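# a small curated list of real drug SMILES for the standardization and
# fingerprint contracts (the naive Bayes machinery itself is tested on
# abstract feature sets and never needs chemistry)
drug_smiles <- c(
  famotidine   = "NC(=N)Nc1nc(CSCCC(=N)NS(N)(=O)=O)cs1",
  bethanechol  = "C[N+](C)(C)CC(C)OC(N)=O",
  prilocaine   = "CCCNC(C)C(=O)Nc1ccccc1C",
  phenylbutyrate = "O=C([O-])CCCc1ccccc1.[Na+]",
  cimetidine   = "Cc1nc[nH]c1CSCCNC(=NC)NC#N",
  aspirin      = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine     = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  ethanol      = "CCO",
  benzene_kek  = "C1=CC=CC=C1",
  benzene_arom = "c1ccccc1",
  troglitazone = "Cc1c(C)c2c(c(C)c1O)CCC(C)(COc1ccc(CC3SC(=O)NC3=O)cc1)O2",
  estradiol    = "C[C@]12CC[C@H]3[C@@H](CCc4cc(O)ccc43)[C@@H]1CC[C@@H]2O",
  resveratrol  = "Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1",
  pyrvinium    = "Cc1cc2cc(/C=C/c3cc(C)n(-c4ccccc4)c3C)ccc2[n+](C)c1N(C)C",
  meglumine    = "CNC[C@H](O)[C@@H](O)[C@H](O)[C@H](O)CO",
  acetate_salt = "CC(=O)[O-].[Na+]",
  salbutamol   = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
  nicotine     = "CN1CCC[C@H]1c1cccnc1",
  ibuprofen    = "CC(C)Cc1ccc(C(C)C(=O)O)cc1",
  glucose      = "OC[C@H]1OC(O)[C@H](O)[C@@H](O)[C@@H]1O")

test_that("standardization aromatizes, strips salts and is idempotent", {
  skip_if_not_installed("ChemmineOB")
  expect_identical(standardize_smiles("C1=CC=CC=C1"),
                   standardize_smiles("c1ccccc1"))
  expect_identical(standardize_smiles("CCO.[Na+].[Cl-]"), "CCO")
  # neutralization of simple +1/-1 charges
  expect_false(grepl("-", standardize_smiles("CC(=O)[O-]"), fixed = TRUE))
  once <- standardize_smiles(drug_smiles)
  twice <- standardize_smiles(once)
  expect_identical(twice, once)
  expect_error(standardize_smiles("not_a_molecule(("), "structure error")
})

test_that("ECFP4 fingerprints are canonical-structure invariants", {
  skip_if_not_installed("ChemmineOB")
  fp <- fingerprint_ecfp4(c(a = "CCO", b = "OCC", c = "CCCO", d = "C"))
  expect_identical(fp$a, fp$b)            # two spellings of ethanol
  expect_gt(length(fp$d), 0L)             # single heavy atom, non-empty
  expect_gt(length(union(setdiff(fp$a, fp$c), setdiff(fp$c, fp$a))), 0L)
  # structureless entries are skipped with a flag
  fp2 <- fingerprint_ecfp4(c(ok = "CCO", missing = ""))
  expect_null(fp2$missing)
  expect_equal(attr(fp2, "structureless"), "missing")
})

test_that("training filter keeps only sub-10uM, confidence 9/10 records", {
  triples <- data.frame(
    compound_id = paste0("c", 1:5), smiles = "",
    target_id = "t1",
    affinity_nM = c(760, 42, 10000, 9999.999, 500),
    confidence = c(9L, 10L, 10L, 9L, 8L),
    stringsAsFactors = FALSE)
  kept <- filter_bioactivities(triples)
  expect_setequal(kept$compound_id, c("c1", "c2", "c4"))
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["affinity"]), 1L)    # the exact-10uM boundary row
  expect_equal(unname(rej["confidence"]), 1L)
})

test_that("the filter is a pure subset whose rows satisfy both predicates", {
  set.seed(31)
  n <- 500
  triples <- data.frame(
    compound_id = sprintf("c%03d", seq_len(n)), smiles = "",
    target_id = sample(paste0("t", 1:5), n, TRUE),
    affinity_nM = 10^runif(n, 0, 5),           # 1 nM .. 100 uM
    confidence = sample(1:10, n, TRUE), stringsAsFactors = FALSE)
  kept <- filter_bioactivities(triples)
  expect_true(all(kept$affinity_nM < 10000))
  expect_true(all(kept$confidence %in% c(9L, 10L)))
  expect_true(nrow(kept) <= n)
  expect_equal(nrow(kept) + sum(attr(kept, "rejections")), n)
  # retained rows are a subset of the input
  expect_true(all(kept$compound_id %in% triples$compound_id))
})

test_that("model counts equal a brute-force tally on a hand-countable set", {
  fps <- list(c1 = c(1L, 2L), c2 = c(2L, 3L), c3 = c(1L, 4L), c4 = c(4L, 5L))
  triples <- data.frame(
    compound_id = c("c1", "c2", "c3", "c4"),
    smiles = "", target_id = c("tA", "tA", "tB", "tB"),
    affinity_nM = 100, confidence = 9L, stringsAsFactors = FALSE)
  models <- train_target_models(triples, fps)
  expect_equal(models$n_total, 4L)
  # brute-force tallies: feature 2 appears in c1, c2 (both tA actives)
  expect_equal(unname(models$targets$tA$a_tf["2"]), 2L)
  expect_equal(unname(models$targets$tA$a_tf["1"]), 1L)
  expect_equal(unname(models$targets$tB$a_tf["4"]), 2L)
  expect_equal(unname(models$t_f["1"]), 2L)     # c1 and c3
  expect_equal(unname(models$t_f["2"]), 2L)
  expect_equal(unname(models$t_f["5"]), 1L)
  expect_equal(models$targets$tA$n_actives, 2L)
})

test_that("duplicated training rows leave all model counts unchanged", {
  fps <- list(c1 = c(1L, 2L), c2 = c(2L, 3L))
  triples <- data.frame(compound_id = c("c1", "c2"), smiles = "",
                        target_id = "tA", affinity_nM = 10, confidence = 9L,
                        stringsAsFactors = FALSE)
  m1 <- train_target_models(triples, fps)
  m2 <- train_target_models(rbind(triples, triples, triples[1, ]), fps)
  expect_identical(m1$targets, m2$targets)
  expect_identical(m1$t_f, m2$t_f)
  expect_identical(m1$n_total, m2$n_total)
})

test_that("single-target training yields one model; missing fingerprints error", {
  fps <- list(c1 = 1L)
  triples <- data.frame(compound_id = "c1", smiles = "", target_id = "tA",
                        affinity_nM = 10, confidence = 9L,
                        stringsAsFactors = FALSE)
  expect_length(train_target_models(triples, fps)$targets, 1L)
  triples2 <- rbind(triples, data.frame(compound_id = "c9", smiles = "",
                                        target_id = "tA", affinity_nM = 10,
                                        confidence = 9L))
  expect_error(train_target_models(triples2, fps), "missing fingerprints.*c9")
})

test_that("scores are additive over features and neutral for unseen features", {
  fps <- list(c1 = c(1L, 2L), c2 = c(1L, 3L), c3 = c(4L, 5L))
  triples <- data.frame(compound_id = c("c1", "c2", "c3"), smiles = "",
                        target_id = c("tA", "tA", "tB"),
                        affinity_nM = 10, confidence = 9L,
                        stringsAsFactors = FALSE)
  models <- train_target_models(triples, fps)
  all_t <- function(fp) score_targets(fp, models, top_k = Inf)
  # additivity: score(f1, f2) = score(f1) + score(f2), exactly
  s12 <- all_t(c(1L, 2L)); s1 <- all_t(1L); s2 <- all_t(2L)
  expect_identical(s12$score[order(s12$target_id)],
                   s1$score[order(s1$target_id)] +
                     s2$score[order(s2$target_id)])
  # unseen feature: T_f = 0 -> log(1/1) = 0 contribution
  s_unseen <- all_t(999L)
  expect_equal(s_unseen$score, c(0, 0))
  expect_true(attr(all_t(integer(0)), "empty_fingerprint"))
  # feature private to tA's actives puts tA above tB
  s <- all_t(1L)
  expect_equal(s$target_id[1], "tA")
  # direct computation of the Laplacian-corrected term:
  # A=2, T_f=2, P(tA)=2/3 -> log(3 / (2*2/3 + 1))
  expect_equal(s$score[s$target_id == "tA"], log(3 / (2 * 2 / 3 + 1)),
               tolerance = 1e-15)
  # per-compound ranks are 1..k without gaps
  expect_equal(s12$rank, seq_len(nrow(s12)))
})

test_that("planted mechanisms are recovered top-1 for >=90% of actives", {
  spec <- fixture_spec(seed = 77)
  bio <- gen_bioactivity_set(spec)
  train <- filter_bioactivities(bio$triples)
  models <- train_target_models(train, bio$fingerprints)
  pred <- predict_targets(bio$fingerprints[train$compound_id], models,
                          top_k = 1L)
  hit <- pred$target_id == bio$truth[pred$compound_id]
  expect_gte(mean(hit), 0.9)
})

test_that("experimental support takes the minimum affinity across assays", {
  pred <- data.frame(compound_id = c("fam", "fam", "x"),
                     target_id = c("H2", "MATE1", "H2"),
                     score = c(3, 2, 1), rank = c(1L, 2L, 1L),
                     stringsAsFactors = FALSE)
  measured <- data.frame(compound_id = c("fam", "fam", "fam"),
                         target_id = c("H2", "MATE1", "MATE1"),
                         affinity_nM = c(42, 760, 9000),
                         stringsAsFactors = FALSE)
  out <- flag_known_targets(pred, measured)
  expect_equal(out$experimental_support_nM, c(42, 760, NA))
})

test_that("target models survive a TSV serialization round trip", {
  spec <- fixture_spec(seed = 5, n_compounds = 30, n_targets = 4)
  bio <- gen_bioactivity_set(spec)
  train <- filter_bioactivities(bio$triples)
  models <- train_target_models(train, bio$fingerprints)
  f <- tempfile(fileext = ".tsv")
  write_target_models(models, f)
  back <- read_target_models(f)
  expect_equal(back$n_total, models$n_total)
  expect_setequal(names(back$targets), names(models$targets))
  fp <- bio$fingerprints[[1]]
  expect_equal(score_targets(fp, back, top_k = Inf)$score,
               score_targets(fp, models, top_k = Inf)$score,
               tolerance = 1e-12)
})
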