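# Deterministic synthetic-data generators. Every external input the pipeline
# reads (two-class expression + phenotype + probe map, compound instance
# signatures, bioactivity training sets) can be generated with known ground
# truth, so the full method is testable without any downloads. All
# generators are pure functions of the fixture spec: identical seed,
# identical output.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Specify a synthetic fixture
#'
#' Bundles the knobs of all generators. Defaults describe a desk-scale
#' emulation of the study design: a two-class expression matrix (stem cells
#' vs target tissue) with planted differential genes, a cohort of compound
#' instances containing planted signature mimics and reversers, and a
#' bioactivity training set whose targets are defined by private fingerprint
#' features.
#'
#' @param seed Integer RNG seed.
#' @param n_genes Gene universe size.
#' @param n_samples_per_class Samples per phenotype class.
#' @param n_de_genes Planted differential genes (half up, half down).
#' @param effect_size Mean log2 shift of planted genes.
#' @param noise_sd Gaussian log2-scale noise standard deviation.
#' @param probe_dup_frac Fraction of genes measured by two probes.
#' @param n_instances Compound instances in the signature cohort.
#' @param n_planted_mimics,n_planted_reversers Planted instances drawing
#'   their signatures from the tissue profile's extreme deciles.
#' @param signature_size Genes per signature side (x, default 50).
#' @param n_compounds,n_targets,features_per_target Bioactivity set shape.
#' @param n_noise_features Size of the shared noise-feature pool.
#' @param noise_features_per_compound Noise features added per fingerprint.
#' @param filter_fail_frac Fraction of bioactivity rows generated to violate
#'   the training filter (affinity or confidence), for filter-path coverage.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_genes = 1000L, n_samples_per_class = 5L,
                         n_de_genes = 100L, effect_size = 2, noise_sd = 0.5,
                         probe_dup_frac = 0.1,
                         n_instances = 100L, n_planted_mimics = 1L,
                         n_planted_reversers = 1L, signature_size = 50L,
                         n_compounds = 200L, n_targets = 20L,
                         features_per_target = 3L, n_noise_features = 50L,
                         noise_features_per_compound = 3L,
                         filter_fail_frac = 0.2) {
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_samples_per_class = as.integer(n_samples_per_class),
               n_de_genes = as.integer(n_de_genes),
               effect_size = as.numeric(effect_size),
               noise_sd = as.numeric(noise_sd),
               probe_dup_frac = as.numeric(probe_dup_frac),
               n_instances = as.integer(n_instances),
               n_planted_mimics = as.integer(n_planted_mimics),
               n_planted_reversers = as.integer(n_planted_reversers),
               signature_size = as.integer(signature_size),
               n_compounds = as.integer(n_compounds),
               n_targets = as.integer(n_targets),
               features_per_target = as.integer(features_per_target),
               n_noise_features = as.integer(n_noise_features),
               noise_features_per_compound = as.integer(noise_features_per_compound),
               filter_fail_frac = as.numeric(filter_fail_frac))
  counts <- c("n_genes", "n_samples_per_class", "n_instances", "n_compounds",
              "n_targets", "features_per_target", "signature_size")
  for (f in counts)
    if (is.na(spec[[f]]) || spec[[f]] < 1L)
      stop("fixture_spec validation error: ", f, " must be a positive count")
  if (spec$n_de_genes > spec$n_genes)
    stop("fixture_spec validation error: n_de_genes exceeds n_genes")
  if (spec$n_planted_mimics + spec$n_planted_reversers > spec$n_instances)
    stop("fixture_spec validation error: planted instances exceed n_instances")
  if (spec$filter_fail_frac < 0 || spec$filter_fail_frac >= 1)
    stop("fixture_spec validation error: filter_fail_frac must be in [0,1)")
  structure(spec, class = "fixture_spec")
}

#' Generate a two-class expression matrix with planted differential genes
#'
#' Emulates a stem-cell-versus-tissue two-class microarray matrix: each gene
#' draws a log-normal baseline (log2 means ~ N(7, 2)) with additive Gaussian
#' log2-scale noise; in the second class, `n_de_genes` planted genes are
#' shifted by the effect size, half up and half down. A configurable
#' fraction of genes is measured by two probes (many-to-one probe map).
#' Values are on log2 scale, so downstream ranking uses `logged = TRUE`.
#'
#' @param spec A [fixture_spec()].
#' @return List with `profile` (probe-level [expression_profile()]), `phen`
#'   ([phenotype_assignment()], classes `STEM`, `TISSUE`), `map`
#'   ([probe_map()]), and `truth` (data.frame of planted genes with
#'   `direction` +1/-1, where +1 means higher in `STEM`).
#' @export
gen_two_class_expression <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    g <- sprintf("G%04d", seq_len(spec$n_genes))
    ns <- spec$n_samples_per_class
    base <- stats::rnorm(spec$n_genes, mean = 7, sd = 2)
    de <- sample(g, spec$n_de_genes)
    n_up <- ceiling(spec$n_de_genes / 2)
    dir_ <- stats::setNames(rep(0, spec$n_genes), g)
    dir_[de[seq_len(n_up)]] <- 1
    dir_[de[-seq_len(n_up)]] <- -1
    # class A = STEM carries the shift, so direction +1 = STEM-high
    mean_a <- base + dir_ * spec$effect_size
    mean_b <- base
    vals <- cbind(
      matrix(stats::rnorm(spec$n_genes * ns, mean_a, spec$noise_sd),
             nrow = spec$n_genes),
      matrix(stats::rnorm(spec$n_genes * ns, mean_b, spec$noise_sd),
             nrow = spec$n_genes))
    samples <- c(sprintf("STEM_%d", seq_len(ns)), sprintf("TISSUE_%d", seq_len(ns)))
    dup <- sample(g, round(spec$probe_dup_frac * spec$n_genes))
    probes <- c(paste0(g, "_at"), paste0(dup, "_x_at"))
    pmat <- rbind(vals, vals[match(dup, g), , drop = FALSE] +
                    matrix(stats::rnorm(length(dup) * 2 * ns, 0, 0.1),
                           nrow = length(dup)))
    profile <- expression_profile(pmat, probes, samples)
    phen <- phenotype_assignment(c("STEM", "TISSUE"), rep(1:2, each = ns))
    map <- probe_map(probes, c(g, dup))
    truth <- data.frame(gene = de, direction = unname(dir_[de]),
                        stringsAsFactors = FALSE)
    list(profile = profile, phen = phen, map = map, truth = truth)
  })
}

#' Generate a cohort of compound-instance signatures
#'
#' Emulates a per-instance compound signature collection against a given
#' tissue profile: planted mimics draw their up set from the profile's top
#' decile and their down set from the bottom decile (so their combined
#' connectivity should be extreme positive), reversers the converse, and
#' background instances draw both sets uniformly.
#'
#' @param spec A [fixture_spec()].
#' @param tissue_ranked A [ranked_genes()] profile of length at least
#'   10 x signature size.
#' @return List with `signatures` (named list of [gene_signature()]) and
#'   `truth` (data.frame `source_id`, `role` in mimic/reverser/background).
#' @export
gen_compound_instances <- function(spec, tissue_ranked) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(tissue_ranked, "ranked_genes"))
  n <- length(tissue_ranked)
  x <- spec$signature_size
  if (n < 10L * x)
    stop("size error: tissue list must hold at least 10 x signature_size genes")
  dec <- n %/% 10L
  top <- tissue_ranked$gene_symbols[seq_len(dec)]
  bottom <- tissue_ranked$gene_symbols[seq.int(n - dec + 1L, n)]
  all_genes <- tissue_ranked$gene_symbols
  with_seed(spec$seed + 1L, {
    roles <- sample(c(rep("mimic", spec$n_planted_mimics),
                      rep("reverser", spec$n_planted_reversers),
                      rep("background",
                          spec$n_instances - spec$n_planted_mimics -
                            spec$n_planted_reversers)))
    ids <- sprintf("inst_%04d", seq_len(spec$n_instances))
    sigs <- lapply(seq_len(spec$n_instances), function(i) {
      if (roles[i] == "mimic") {
        up <- sample(top, x); dn <- sample(bottom, x)
      } else if (roles[i] == "reverser") {
        up <- sample(bottom, x); dn <- sample(top, x)
      } else {
        pick <- sample(all_genes, 2L * x)
        up <- pick[seq_len(x)]; dn <- pick[-seq_len(x)]
      }
      gene_signature(up, dn, source_id = ids[i])
    })
    names(sigs) <- ids
    list(signatures = sigs,
         truth = data.frame(source_id = ids, role = roles,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic bioactivity training set
#'
#' Emulates a filtered bioactivity extract with known mechanism ground
#' truth: each target owns `features_per_target` private fingerprint
#' features; each compound is active on one true target and its fingerprint
#' carries that target's private features plus a few features from a shared
#' noise pool. A requested fraction of rows is generated to violate the
#' training filter (affinity at or above 10 uM, or confidence below 9).
#' Fingerprints are abstract integer feature sets, not chemistry-derived,
#' so naive Bayes behaviour is tested independently of any toolkit.
#'
#' @param spec A [fixture_spec()].
#' @return List with `triples` (bioactivity data.frame, nM affinities),
#'   `fingerprints` (named list of integer feature ids) and `truth` (named
#'   character vector compound_id -> true target_id).
#' @export
gen_bioactivity_set <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed + 2L, {
    targets <- sprintf("T%03d", seq_len(spec$n_targets))
    private <- stats::setNames(lapply(seq_len(spec$n_targets), function(t)
      seq.int((t - 1L) * spec$features_per_target + 1L,
              t * spec$features_per_target)), targets)
    noise_pool <- 100000L + seq_len(spec$n_noise_features)
    compounds <- sprintf("C%04d", seq_len(spec$n_compounds))
    true_target <- sample(targets, spec$n_compounds, replace = TRUE)
    fingerprints <- stats::setNames(lapply(seq_len(spec$n_compounds), function(i) {
      extra <- if (spec$noise_features_per_compound > 0 &&
                   spec$n_noise_features > 0)
        sample(noise_pool, min(spec$noise_features_per_compound,
                               spec$n_noise_features)) else integer(0)
      sort(as.integer(c(private[[true_target[i]]], extra)))
    }), compounds)
    n_fail <- round(spec$filter_fail_frac * spec$n_compounds)
    fail <- seq_len(spec$n_compounds) %in%
      sample(spec$n_compounds, n_fail)
    affinity <- 10^stats::runif(spec$n_compounds, 0, 4)  # 1 nM .. 10 uM
    confidence <- sample(9:10, spec$n_compounds, replace = TRUE)
    if (n_fail > 0) {
      mode_aff <- stats::runif(n_fail) < 0.5
      which_fail <- which(fail)
      affinity[which_fail[mode_aff]] <-
        10^stats::runif(sum(mode_aff), 4, 5)     # 10 uM .. 100 uM
      confidence[which_fail[!mode_aff]] <-
        sample(1:8, sum(!mode_aff), replace = TRUE)
    }
    triples <- data.frame(compound_id = compounds, smiles = "",
                          target_id = true_target,
                          affinity_nM = affinity, confidence = confidence,
                          stringsAsFactors = FALSE)
    list(triples = triples, fingerprints = fingerprints,
         truth = stats::setNames(true_target, compounds))
  })
}

#' Write a full fixture set to disk in the standard formats
#'
#' Materializes one fixture spec as the files a real analysis would read:
#' `expression.gct`, `phenotype.cls`, `probes.chip`, `signatures.gmt`,
#' `bioactivities.tsv`, `compounds.tsv`, plus `truth_*.tsv` tables.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- gen_two_class_expression(spec)
  write_gct(expr$profile, file.path(dir, "expression.gct"))
  write_cls(expr$phen, file.path(dir, "phenotype.cls"))
  write_chip(expr$map, file.path(dir, "probes.chip"))
  gene_level <- collapse_probes(expr$profile, expr$map)
  ranked <- differential_ranking(gene_level, expr$phen,
                                 metric = "signal2noise")
  write_rnk(ranked, file.path(dir, "tissue_profile.rnk"))
  inst <- gen_compound_instances(spec, ranked)
  write_signatures_gmt(inst$signatures, file.path(dir, "signatures.gmt"))
  bio <- gen_bioactivity_set(spec)
  write_tsv(bio$triples, file.path(dir, "bioactivities.tsv"))
  comp <- data.frame(compound_id = inst$truth$source_id,
                     instance_id = inst$truth$source_id,
                     smiles = "", cell_line = "SYNTH",
                     therapeutic_flag = FALSE, stringsAsFactors = FALSE)
  write_tsv(comp, file.path(dir, "compounds.tsv"))
  write_tsv(expr$truth, file.path(dir, "truth_de_genes.tsv"))
  write_tsv(inst$truth, file.path(dir, "truth_instances.tsv"))
  write_tsv(data.frame(compound_id = names(bio$truth),
                       target_id = unname(bio$truth),
                       stringsAsFactors = FALSE),
            file.path(dir, "truth_targets.tsv"))
  invisible(dir)
}
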