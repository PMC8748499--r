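make_hotspot <- function(R_vec, carriers_list, pos = NULL) {
  n <- length(R_vec)
  if (is.null(pos)) pos <- seq(1500L, by = 10L, length.out = n)
  structure(list(chrom = "c", start = 1001L, end = 3000L,
                 sites = data.table::data.table(
                   chrom = "c", pos = pos, ref = "C", alt = "T",
                   R = R_vec, carriers = carriers_list),
                 selected_sub_windows = 1L,
                 sub_window_starts = 1001L, load = 1),
            class = "hotspot_region")
}

test_that("eligibility follows the recurrence/total rules", {
  h <- function(R) make_hotspot(R, lapply(R, function(r) sprintf("T%d", 1:r)))
  expect_true(eligibility_check(h(6L)))                 # one site R = 6
  expect_true(eligibility_check(h(c(3L, 4L, 3L))))      # 10 variants, R >= 3
  expect_false(eligibility_check(h(c(5L, 4L))))         # 9 variants, R = 5
  expect_false(eligibility_check(h(c(2L, 2L, 2L, 2L, 2L))))  # 10 but R < 3
})

test_that("site weights are recurrence times median carrier load", {
  prof <- data.frame(tumor_id = c("Ta", "Tb", "Tc"), entity = "e",
                     sex = "female", total_load = c(100L, 200L, 300L))
  h <- make_hotspot(c(3L, 2L),
                    list(c("Ta", "Tb", "Tc"), c("Ta", "Tb")))
  w <- variant_site_weights(h, prof)
  expect_equal(w, c(3 * 200, 2 * 150))   # odd median; even-count midpoint
  h1 <- make_hotspot(1L, list("Ta"))
  expect_equal(variant_site_weights(h1, prof), 100)   # R = 1, single load
  # a carrier without a profile is an error
  h2 <- make_hotspot(1L, list("Tz"))
  expect_error(variant_site_weights(h2, prof), "without a tumor profile")
})

test_that("the null model adjusts for entity, load and sex", {
  prof <- toy_profiles(400, seed = 21)
  # constant exposure: all residuals zero
  E0 <- matrix(0.25, 400, 1, dimnames = list(prof$tumor_id, "S"))
  nm0 <- fit_null_model(E0, prof, "S")
  expect_lt(max(abs(nm0$residuals)), 1e-12)
  # known nvar coefficient is recovered within its standard error range
  nm <- sighotspot:::with_seed(22, {
    y <- 0.3 + 0.001 * prof$total_load + rnorm(400, 0, 0.05)
    fit_null_model(matrix(y, dimnames = list(prof$tumor_id, "S")), prof, "S")
  })
  expect_lt(abs(nm$coefficients["nvar"] - 0.001), 3e-5)
  # single-level factors are dropped with a warning, model still fits
  prof1 <- prof; prof1$entity <- "only"
  expect_warning(nm1 <- fit_null_model(E0, prof1, "S"), "entity")
  expect_false(any(grepl("entity", colnames(nm1$X))))
})

test_that("kernel p is invariant to weight rescaling; direction is signed", {
  prof <- toy_profiles(300, seed = 23)
  G <- toy_genotypes(300, c(15, 8, 4), seed = 24)
  nm <- toy_null_model(prof, seed = 25)
  t1 <- kernel_association_test(G, nm, c(100, 50, 10))
  t2 <- kernel_association_test(G, nm, 7 * c(100, 50, 10))
  expect_equal(t1$p_raw, t2$p_raw, tolerance = 1e-9)
  expect_equal(t1$n_sites, 3L)
  # planted positive and negative shifts give the corresponding sign
  y <- nm$y
  carriers <- which(G[, 1] == 1)
  Eup <- matrix(y, dimnames = list(prof$tumor_id, "S"))
  Eup[carriers, 1] <- Eup[carriers, 1] + 0.3
  tu <- kernel_association_test(G, fit_null_model(Eup, prof, "S"),
                                c(100, 50, 10))
  expect_equal(tu$direction, "positive")
  expect_lt(tu$p_raw, 1e-6)
  Edn <- matrix(y, dimnames = list(prof$tumor_id, "S"))
  Edn[carriers, 1] <- Edn[carriers, 1] - 0.3
  td <- kernel_association_test(G, fit_null_model(Edn, prof, "S"),
                                c(100, 50, 10))
  expect_equal(td$direction, "negative")
  # all-zero genotype matrices are rejected
  expect_error(kernel_association_test(G * 0L, nm, c(1, 1, 1)),
               "no carriers")
})

test_that("resampling calibration brackets and floors correctly", {
  prof <- toy_profiles(200, seed = 26)
  nm <- toy_null_model(prof, seed = 27)
  G <- toy_genotypes(200, c(20, 6), seed = 28)
  # a strongly associated response: replicate min-p never beats observed
  y2 <- nm$y; y2[G[, 1] == 1] <- y2[G[, 1] == 1] + 1
  nm2 <- fit_null_model(matrix(y2, dimnames = list(prof$tumor_id, "S")),
                        prof, "S")
  t2 <- kernel_association_test(G, nm2, c(20, 6) * 100)
  rc <- resample_calibrate(t2, B = 999L, b_max = 999L, seed = 5)
  expect_equal(rc$p_resampled, 1 / 1000)
  # an unassociated response stays near its raw p and respects bounds
  t0 <- kernel_association_test(G, nm, c(20, 6) * 100)
  rc0 <- resample_calibrate(t0, B = 999L, seed = 6)
  expect_gte(rc0$p_resampled, 1 / 1000)
  expect_lte(rc0$p_resampled, 1)
  expect_lt(abs(rc0$p_resampled - t0$p_raw), 0.12)
  # adaptive escalation triggers only for tiny raw p
  expect_equal(rc0$B_used, 999L)
  rc2 <- resample_calibrate(t2, B = 999L, b_max = 9999L, seed = 7)
  expect_equal(rc2$B_used, 9999L)
  expect_equal(rc2$p_resampled, 1e-4)
})

test_that("under the null, resampled p tracks raw p", {
  prof <- toy_profiles(150, seed = 30)
  diffs <- vapply(1:40, function(i) {
    nm <- toy_null_model(prof, seed = 100 + i)
    G <- toy_genotypes(150, c(12, 7), seed = 200 + i)
    tt <- kernel_association_test(G, nm, c(12, 7) * 50)
    rc <- resample_calibrate(tt, B = 999L, b_max = 999L, seed = i)
    abs(rc$p_resampled - tt$p_raw)
  }, numeric(1))
  expect_lt(mean(diffs), 0.05)
})

test_that("Bonferroni adjustment and ordering invariants hold", {
  expect_equal(bonferroni_adjust(c(0.0005, 0.02), 100), c(0.05, 1))
  expect_equal(bonferroni_adjust(0.3, 1), 0.3)
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "at least")
})

test_that("inflation lambda is exact at its anchor and flags inflation", {
  expect_equal(inflation_lambda(rep(0.5, 20))$lambda, 1)
  expect_true(inflation_lambda(rep(1e-10, 20))$flagged)
  l <- sighotspot:::with_seed(31, inflation_lambda(runif(10000)))
  expect_gt(l$lambda, 0.95); expect_lt(l$lambda, 1.05)
  expect_error(inflation_lambda(c(rep(0.5, 10), 0)), "\\(0, 1\\]")
  expect_error(inflation_lambda(rep(0.5, 5)), "at least 10")
})

test_that("site perturbation isolates the causal site", {
  prof <- toy_profiles(300, seed = 33)
  # two identical sites have equal ratios by exchangeability
  carriers <- sample(300, 12)
  G <- matrix(0L, 300, 2); G[carriers, ] <- 1L
  colnames(G) <- c("a", "b")
  nm <- toy_null_model(prof, seed = 34)
  tt <- kernel_association_test(G, nm, c(5, 5))
  pp <- perturb_sites(tt, G, nm, c(5, 5))
  expect_equal(pp$ratio[1], pp$ratio[2], tolerance = 1e-8)
  # single-site hotspots get the trivial profile
  G1 <- G[, 1, drop = FALSE]
  t1 <- kernel_association_test(G1, nm, 5)
  expect_equal(perturb_sites(t1, G1, nm, 5)$ratio, 1)
  # a planted causal site among passengers attains the top ratio
  hits <- vapply(1:20, function(i) {
    G <- toy_genotypes(300, c(10, 10, 10, 10, 10), seed = 400 + i)
    nm0 <- toy_null_model(prof, seed = 500 + i)
    y <- nm0$y; y[G[, 3] == 1] <- y[G[, 3] == 1] + 3 * sqrt(nm0$sigma2)
    nmc <- fit_null_model(matrix(y, dimnames = list(prof$tumor_id, "S")),
                          prof, "S")
    tc <- kernel_association_test(G, nmc, rep(10, 5))
    pp <- perturb_sites(tc, G, nmc, rep(10, 5))
    which.max(pp$ratio) == 3
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
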