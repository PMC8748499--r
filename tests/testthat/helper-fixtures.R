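# Shared fixtures, built in code at test time.

# Deterministic toy genome: chr1 = fixed 60 bp sequence.
toy_genome <- function() {
  list(chr1 = paste0("ACATGGCTAGCTAGCTTACGATCGATCGGCTA",
                     "GCATCGATTTACGGATCCGATCGATCAGT"))
}

# Small variant table as a data.table.
toy_variants <- function() {
  data.table::data.table(
    tumor_id = c("TA", "TA", "TB", "TB", "TC"),
    chrom = "chr1",
    pos = c(3L, 10L, 3L, 20L, 30L),
    ref = c("A", "G", "A", "C", "C"),
    alt = c("G", "T", "G", "T", "A"))
}

# Covariate scaffold for association tests: n tumors, three entities,
# two sexes, log-normal-ish loads.
toy_profiles <- function(n, seed = 1) {
  sighotspot:::with_seed(seed, data.frame(
    tumor_id = sprintf("T%04d", seq_len(n)),
    entity = sample(c("entA", "entB", "entC"), n, replace = TRUE),
    sex = sample(c("female", "male"), n, replace = TRUE),
    total_load = pmax(50L, as.integer(round(stats::rlnorm(n, log(2000), 1)))),
    stringsAsFactors = FALSE))
}

# Gaussian-response null model on the toy covariates: y depends on the
# covariates but not on any genotype.
toy_null_model <- function(profiles, seed = 1, sd = 0.1) {
  sighotspot:::with_seed(seed, {
    y <- 0.3 + 0.02 * (profiles$entity == "entB") +
      1e-6 * profiles$total_load + stats::rnorm(nrow(profiles), 0, sd)
    E <- matrix(y, ncol = 1, dimnames = list(profiles$tumor_id, "SigX"))
    fit_null_model(E, profiles, "SigX")
  })
}

# Random binary genotype matrix: m sites with the given carrier counts.
toy_genotypes <- function(n, carriers_per_site, seed = 1) {
  sighotspot:::with_seed(seed, {
    G <- sapply(carriers_per_site, function(k) {
      g <- integer(n); g[sample.int(n, k)] <- 1L; g
    })
    matrix(G, nrow = n,
           dimnames = list(NULL, paste0("s", seq_along(carriers_per_site))))
  })
}

# Literal evaluation of the three hotspot pruning conditions, used as
# the independent oracle for select_hotspot_windows.
brute_force_select <- function(L) {
  sel <- integer(0)
  for (i in seq_along(L)) {
    c5 <- L[i] >= max(L) / 2
    c6 <- L[i] > 3 * mean(L)
    c7 <- L[i] >= mean(L) + stats::sd(L) * 3
    if (length(L) == 1) c7 <- L[i] >= mean(L)
    if (c5 && c6 && c7) sel <- c(sel, i)
  }
  sel
}

# Small default cohort config for pipeline tests (reduced sizes; the
# acceptance suite exercises the full default conditions).
small_cohort_config <- function(seed, n_tumors = 150, genome_length = 2e6,
                                hotspots = NULL, load_meanlog = log(800)) {
  cohort_config(n_tumors = n_tumors, genome_length = genome_length,
                load_meanlog = load_meanlog, hotspots = hotspots,
                seed = seed, genome_seed = 20260901L)
}
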