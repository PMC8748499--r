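one_state_track <- function(state, lo = 1L, hi = 1000L) {
  data.frame(chrom = "c", start = lo, end = hi, state = state,
             stringsAsFactors = FALSE)
}

test_that("chromatin annotation applies the 1:2 ratio rule", {
  mk <- function(n_state, n_bg, state = "EnhA1", bg = "Tx") {
    c(lapply(seq_len(n_state), function(i) one_state_track(state)),
      lapply(seq_len(n_bg), function(i) one_state_track(bg)))
  }
  # 40 enhancer vs 60 background: 0.667 > 0.5 -> enhancer
  expect_true(annotate_chromhmm("c", 500L, mk(40, 60))$enhancer)
  # 10 vs 80: 0.125 -> not enhancer
  expect_false(annotate_chromhmm("c", 500L, mk(10, 80))$enhancer)
  # positive states with zero background: unbounded ratio -> flagged
  expect_true(annotate_chromhmm("c", 500L, mk(5, 0))$enhancer)
  # TSS rule with its own state/background sets
  a <- annotate_chromhmm("c", 500L, mk(30, 10, state = "TssA", bg = "Tx"))
  expect_true(a$tss)
  # a site outside every track gets both flags FALSE
  out <- annotate_chromhmm("c", 5000L, mk(5, 5))
  expect_false(out$enhancer); expect_false(out$tss)
  # quiescent state counts for neither flag nor background
  q <- annotate_chromhmm("c", 500L, mk(1, 0, state = "Quies", bg = "Quies"))
  expect_false(q$enhancer)
})

test_that("coding flags and nearest genes resolve deterministically", {
  genes <- data.frame(chrom = "c", start = c(1000L, 3000L),
                      end = c(2000L, 3999L), gene = c("B", "A"))
  cds <- data.frame(chrom = "c", start = 1200L, end = 1400L, gene = "B")
  inside <- annotate_coding("c", 1300L, genes, cds)
  expect_true(inside$coding)
  expect_equal(inside$nearest_gene, "B")
  # intergenic: nearest by genomic distance
  mid <- annotate_coding("c", 2400L, genes, cds)
  expect_false(mid$coding)
  expect_equal(mid$nearest_gene, "B")       # 400 vs 600 bp away
  # equidistant tie resolves alphabetically (with a note)
  expect_message(tie <- annotate_coding("c", 2500L, genes, cds), "tie")
  expect_equal(tie$nearest_gene, "A")
  # empty gene model
  none <- annotate_coding("c", 10L, genes[0, ], NULL)
  expect_true(is.na(none$nearest_gene))
})

test_that("permutation enrichment matches an exhaustive binomial oracle", {
  # 1000 bp toy genome, one 100 bp element, 2 hotspot sites inside it
  elements <- data.frame(chrom = "c", start = 100L, end = 200L)
  map <- data.frame(chrom = "c", start = 0L, end = 1000L, score = 1)
  sites <- data.frame(chrom = "c", pos = c(150L, 160L))
  res <- permutation_enrichment(sites, elements, map, n_perm = 20000L,
                                seed = 3)
  # exact: P(overlap >= 2) with overlap ~ Binomial(2, 0.1)
  p_exact <- 0.1^2
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p - p_exact), 4 * se + 1 / 20001)
  expect_equal(res$observed, 2L)
  # elements covering the whole mappable genome: p = 1
  all_el <- data.frame(chrom = "c", start = 0L, end = 1000L)
  expect_equal(permutation_enrichment(sites, all_el, map, n_perm = 500L,
                                      seed = 1)$p, 1)
  # observed exceeding every permutation hits the formula floor
  far <- data.frame(chrom = "c", start = 990L, end = 991L)
  sites1 <- data.frame(chrom = "c", pos = 991L)
  res2 <- permutation_enrichment(sites1, far, map, n_perm = 999L, seed = 2)
  expect_gte(res2$p, 1 / 1000)
  # mappability filter can empty the universe
  map0 <- data.frame(chrom = "c", start = 0L, end = 1000L, score = 0.1)
  expect_error(permutation_enrichment(sites, elements, map0),
               "no mappable territory")
})

test_that("permutation p only counts the mappable universe", {
  # element in unmappable territory can never be hit
  elements <- data.frame(chrom = "c", start = 100L, end = 200L)
  map <- data.frame(chrom = "c", start = c(0L, 500L), end = c(50L, 1000L),
                    score = c(1, 1))
  sites <- data.frame(chrom = "c", pos = 700L)
  res <- permutation_enrichment(sites, elements, map, n_perm = 200L,
                                seed = 4)
  expect_equal(res$observed, 0L)
  expect_equal(res$perm_mean, 0)
  expect_equal(res$mappable_bp, 50 + 500)
})

test_that("hypergeometric enrichment equals exact enumeration", {
  targets <- paste0("g", 1:5)
  hits <- paste0("g", c(1:4))
  res <- hypergeometric_enrichment(hits, targets, background = 20L)
  expect_equal(res$p, 5 / 4845, tolerance = 1e-12)   # C(5,4)C(15,0)/C(20,4)
  # full enumeration oracle for all overlap values at N <= 25
  exact_tail <- function(x, K, n, N) {
    sum(sapply(x:min(K, n), function(i)
      choose(K, i) * choose(N - K, n - i))) / choose(N, n)
  }
  set.seed(9)
  for (i in 1:20) {
    N <- sample(10:25, 1); K <- sample(1:(N - 1), 1); n <- sample(1:N, 1)
    ov <- sample(0:min(K, n), 1)
    p1 <- phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    expect_equal(p1, exact_tail(ov, K, n, N), tolerance = 1e-12)
  }
  # zero overlap is never significant
  expect_equal(hypergeometric_enrichment("x", targets, 20L)$p, 1)
  # default background is 21000
  expect_equal(hypergeometric_enrichment(hits, targets)$N, 21000L)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  # order invariance
  p <- c(0.2, 0.001, 0.06, 0.01)
  o <- sample(4)
  expect_equal(bh_adjust(p)[o], bh_adjust(p[o]))
})

test_that("driver-associated classification uses all three gates strictly", {
  expect_true(classify_driver_associated_signature(0.001, 0.0005, 5))
  expect_false(classify_driver_associated_signature(0.001, 0.0005, 3))
  expect_false(classify_driver_associated_signature(0.2, 0.0005, 5))
  expect_false(classify_driver_associated_signature(0.001, 0.2, 5))
  # boundary: q exactly at alpha is not significant
  expect_false(classify_driver_associated_signature(0.05, 0.001, 5))
})

test_that("putative-driver calls gate on the signature and any criterion", {
  # full truth table over the four criteria and the signature gate
  grid <- expand.grid(enh = c(TRUE, FALSE), tss = c(TRUE, FALSE),
                      cod = c(TRUE, FALSE), expr = c(TRUE, FALSE, NA),
                      rec = c(12L, 5L), gate = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    call <- classify_putative_driver(g$enh, g$tss, g$cod,
                                     if (is.na(g$expr)) NULL else g$expr,
                                     g$rec, g$gate)
    any_crit <- isTRUE(g$enh) || isTRUE(g$tss) || isTRUE(g$cod) ||
      isTRUE(g$expr) || g$rec >= 10L
    expect_equal(call$putative_driver, g$gate && any_crit)
    if (!g$gate) expect_false(call$putative_driver)   # gate property
  }
  # criteria bookkeeping
  call <- classify_putative_driver(FALSE, FALSE, FALSE, NULL, 10L, TRUE)
  expect_equal(call$criteria, "recurrence")
})
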