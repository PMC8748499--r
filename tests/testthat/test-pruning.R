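test_that("tumor weights are 1/log2(load) with a clamp at 2", {
  expect_equal(tumor_weight(2L), 1)
  expect_equal(tumor_weight(1024L), 0.1)
  expect_warning(w <- tumor_weight(1L), "clamped")
  expect_equal(w, 1)
})

test_that("entity restriction applies the 5%/2% positivity thresholds", {
  profiles <- data.frame(
    tumor_id = sprintf("T%03d", 1:200),
    entity = rep(c("high", "low"), each = 100),
    sex = "female", total_load = 100L)
  posm <- matrix(FALSE, 200, 1, dimnames = list(profiles$tumor_id, "S1"))
  posm[1:6, 1] <- TRUE      # entity "high": 6/100 positive
  posm[101:103, 1] <- TRUE  # entity "low": 3/100 positive
  v <- data.table::data.table(tumor_id = c("T001", "T101"), chrom = "c",
                              pos = c(1L, 2L), ref = "C", alt = "T")
  vn <- restrict_entities(v, posm, profiles, "S1", mode = "normal")
  expect_equal(vn$tumor_id, "T001")                 # only >=5% entity kept
  vw <- restrict_entities(v, posm, profiles, "S1", mode = "wide")
  expect_setequal(vw$tumor_id, c("T001", "T101"))   # 2% keeps both
  # zero-positive entity dropped in both modes
  posm[, 1] <- FALSE
  expect_equal(nrow(restrict_entities(v, posm, profiles, "S1", "wide")), 0L)
})

test_that("scan windows tile half-overlapping from 1 and enforce min 6", {
  v <- data.table::data.table(
    tumor_id = "T", chrom = "c",
    pos = c(seq(100, 600, 100), seq(2100, 2500, 100)),  # 6 then 5 records
    ref = "C", alt = "T")
  w <- genome_scan_windows(v, c(c = 5000L))
  # starts tile {1, 1001, 2001, 3001}; only [1,2000] holds >= 6 records
  expect_equal(w$start, 1L)
  expect_equal(w$end, 2000L)
  expect_equal(w$n_variants, 6L)
  # boundary: exactly 6 records retained, 5 discarded
  w2 <- genome_scan_windows(v, c(c = 5000L), min_variants = 5L)
  expect_equal(w2$start, c(1L, 1001L, 2001L))
  # tiling convention on a bare 5 kb chromosome
  v3 <- data.table::data.table(tumor_id = "T", chrom = "c",
                               pos = seq(1L, 4901L, 100L), ref = "C",
                               alt = "T")
  w3 <- genome_scan_windows(v3, c(c = 5000L), min_variants = 1L)
  expect_equal(w3$start, c(1L, 1001L, 2001L, 3001L))
  expect_equal(w3$end[4], 5000L)
})

test_that("binning puts interior variants into exactly two sub-windows", {
  g <- bin_variants(pos = 1016L, tumor = "T", start = 1001L, end = 3000L)
  # offset 16 within the region: sub-windows [1-30] and [16-45]
  expect_setequal(g$win_idx, c(1L, 2L))
  # a variant in the first 15 bp lies in one sub-window only
  g2 <- bin_variants(pos = 1005L, tumor = "T", start = 1001L, end = 3000L)
  expect_equal(g2$win_idx, 1L)
  # empty region gives an all-zero grid
  g3 <- bin_variants(integer(0), character(0), 1L, 300L)
  expect_equal(nrow(g3$l_it), 0L)
  expect_equal(weighted_load(g3, c(T1 = 1)), rep(0, g3$n_sub))
  # non-overlapping (odd-indexed) sub-windows partition the region:
  # summed counts equal the variant count
  set.seed(3)
  pos <- sample(1001:2990, 200, replace = TRUE)
  g4 <- bin_variants(pos, rep("T", 200), 1001L, 3000L)
  odd <- g4$l_it[g4$l_it$sub_window %% 2 == 1, ]
  expect_equal(sum(odd$count), 200L)
})

test_that("weighted load is the weight-weighted bin sum and is linear", {
  g <- bin_variants(pos = c(10L, 12L, 11L, 13L), start = 1L, end = 60L,
                    tumor = c("T1", "T1", "T2", "T2"))
  L <- weighted_load(g, c(T1 = 1, T2 = 0.5))
  expect_equal(L[1], 1 * 2 + 0.5 * 2)   # both tumors' pairs in sub-window 1
  expect_equal(weighted_load(g, c(T1 = 2, T2 = 1)), 2 * L)
  expect_error(weighted_load(g, c(T1 = 1)), "missing tumor weight")
})

test_that("hotspot selection matches the three-condition rule", {
  # single dominant bin among 20 flat ones
  expect_equal(select_hotspot_windows(c(20, rep(1, 20))), 1L)
  # condition 7 (mean + 3 sd) rejects a short spiky vector
  expect_equal(length(select_hotspot_windows(c(10, 1, 1, 1, 1))), 0L)
  # constant positive vectors never select (L > 3*mean impossible)
  expect_equal(length(select_hotspot_windows(rep(5, 10))), 0L)
  # invariance under positive rescaling
  set.seed(4)
  for (i in 1:25) {
    L <- rexp(sample(2:50, 1))
    expect_equal(select_hotspot_windows(L), select_hotspot_windows(7.3 * L))
  }
})

test_that("selection equals the literal brute-force evaluation", {
  set.seed(5)
  for (i in 1:200) {
    L <- switch(sample(3, 1),
                rexp(sample(2:50, 1)),
                rpois(sample(2:50, 1), 2) + 0.0,
                c(rep(0, sample(1:30, 1)), rexp(3, 1 / 10)))
    expect_equal(select_hotspot_windows(L), brute_force_select(L))
  }
})

test_that("region pruning returns recurrent clusters and nothing else", {
  profiles <- data.frame(tumor_id = sprintf("T%02d", 1:20), entity = "e",
                         sex = "female", total_load = 1000L)
  w <- stats::setNames(tumor_weight(profiles$total_load), profiles$tumor_id)
  # one site shared by 8 tumors among scattered singletons
  set.seed(6)
  single <- data.table::data.table(
    tumor_id = sprintf("T%02d", 9:20), chrom = "c",
    pos = sample(c(1001:1400, 1600:3000), 12), ref = "C", alt = "T")
  recur <- data.table::data.table(
    tumor_id = sprintf("T%02d", 1:8), chrom = "c", pos = 1500L,
    ref = "C", alt = "T")
  hs <- prune_region("c", 1001L, 3000L, rbind(single, recur), w)
  expect_s3_class(hs, "hotspot_region")
  expect_true(1500L %in% hs$sites$pos)
  expect_equal(hs$sites$R[hs$sites$pos == 1500L], 8L)
  # every member site lies inside a selected sub-window
  sel_starts <- hs$sub_window_starts
  expect_true(all(sapply(hs$sites$pos, function(p)
    any(p >= sel_starts & p <= sel_starts + 29))))
  # evenly scattered singletons (no cluster) prune to nothing
  flat <- data.table::data.table(
    tumor_id = sprintf("T%02d", 9:20), chrom = "c",
    pos = as.integer(round(seq(1010, 2990, length.out = 12))), ref = "C",
    alt = "T")
  hs2 <- prune_region("c", 1001L, 3000L, flat, w)
  expect_null(hs2)
  # empty region prunes to nothing
  empty <- single[0]
  expect_null(prune_region("c", 1001L, 3000L, empty, w))
})

test_that("recurrence is substitution-specific by default", {
  profiles <- data.frame(tumor_id = sprintf("T%02d", 1:10), entity = "e",
                         sex = "female", total_load = 1000L)
  w <- stats::setNames(tumor_weight(profiles$total_load), profiles$tumor_id)
  v <- data.table::data.table(
    tumor_id = sprintf("T%02d", 1:10), chrom = "c", pos = 1500L,
    ref = "C", alt = rep(c("T", "G"), each = 5))
  hs <- prune_region("c", 1001L, 3000L, v, w)
  expect_equal(sort(hs$sites$R), c(5L, 5L))
  hs2 <- prune_region("c", 1001L, 3000L, v, w, recurrence_by = "position")
  expect_equal(hs2$sites$R, 10L)
})
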