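test_that("cohort simulation is deterministic under a fixed seed", {
  cfg <- small_cohort_config(seed = 77, n_tumors = 40,
                             genome_length = 300000L,
                             load_meanlog = log(200))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$exposures_true, b$exposures_true)
  expect_identical(a$profiles, b$profiles)
})

test_that("simulated tables satisfy the package contracts", {
  hs <- data.frame(position = 150000, signature = "SigS2",
                   effect_size = 2, carrier_fraction = 0.2)
  cfg <- small_cohort_config(seed = 78, n_tumors = 50,
                             genome_length = 300000L,
                             load_meanlog = log(200), hotspots = hs)
  sim <- simulate_cohort(cfg)
  expect_silent(validate_variant_table(sim$variants))
  # loads equal per-tumor record counts (conservation)
  expect_equal(sum(sim$profiles$total_load), nrow(sim$variants))
  # exposures are normalized
  expect_true(all(abs(rowSums(sim$exposures_true) - 1) < 1e-8))
  # every placed variant matches the reference base
  g <- sim$genome$chrS
  idx <- sample(nrow(sim$variants), 200)
  expect_true(all(substring(g, sim$variants$pos[idx],
                            sim$variants$pos[idx]) == sim$variants$ref[idx]))
  # truth manifest carriers all carry the planted substitution
  t1 <- sim$truth$hotspots[[1]]
  expect_setequal(t1$carriers_observed, t1$carriers)
  carried <- sim$variants[sim$variants$pos == t1$pos &
                            sim$variants$alt == t1$alt, ]
  expect_true(all(t1$carriers %in% carried$tumor_id))
})

test_that("null cohorts decouple planted genotypes from exposures", {
  hs <- data.frame(position = c(1e5, 2e5), signature = "SigS1",
                   effect_size = 3, carrier_fraction = 0.2)
  cfg <- small_cohort_config(seed = 79, n_tumors = 60,
                             genome_length = 300000L,
                             load_meanlog = log(200), hotspots = hs)
  null <- simulate_null_cohort(cfg)
  expect_true(all(vapply(null$truth$hotspots, function(h)
    h$effect_size == 0, logical(1))))
  # carriers still share the site
  t1 <- null$truth$hotspots[[1]]
  expect_gte(length(t1$carriers_observed), 10)
  # carrier exposures are not shifted: same Dirichlet population
  E <- null$exposures_true
  carr <- rownames(E) %in% t1$carriers
  expect_lt(abs(mean(E[carr, "SigS1"]) - mean(E[!carr, "SigS1"])), 0.1)
})

rdirichlet_local <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha),
                            shape = rep(alpha, each = n)), n)
  x / rowSums(x)
}

test_that("exposure recovery improves with mutation load", {
  S <- make_synthetic_signatures(4, seed = 81)
  err_at <- function(n_mut) {
    sighotspot:::with_seed(82, {
      E <- rdirichlet_local(30, c(4, 3, 2, 1))
      P <- E %*% S
      cat96 <- t(apply(P, 1, function(p) rmultinom(1, n_mut, p)))
      mean(rowSums(abs(fit_exposures(cat96, S) - E)))
    })
  }
  e_small <- err_at(100)
  e_large <- err_at(10000)
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.05)
})

test_that("written cohorts can be reloaded by the pipeline readers", {
  cfg <- small_cohort_config(seed = 83, n_tumors = 30,
                             genome_length = 200000L,
                             load_meanlog = log(150))
  sim <- simulate_cohort(cfg)
  dir <- tempfile()
  write_cohort(sim, dir)
  v <- read_variant_table(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(sim$variants))
  S <- read_signature_matrix(file.path(dir, "signatures.tsv"))
  expect_equal(S, sim$signatures, tolerance = 1e-12)
  g <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  expect_equal(as.character(g[["chrS"]]), sim$genome$chrS)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$seed, cfg$seed)
})
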