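## End-to-end orchestration: catalog -> exposures -> scan -> kernel test
## -> calibration -> Bonferroni -> inflation filter -> perturbation ->
## annotation -> driver classification, with a run manifest.

#' Scan a cohort for signature-associated hotspots
#'
#' Runs the discovery pipeline for one or more signatures on in-memory
#' cohort objects.  For each signature: restrict variants to entities
#' with sufficient signature positivity, tile candidate windows, prune
#' each window to hotspot sub-windows, test eligible hotspots with the
#' kernel association test, calibrate by resampling, and Bonferroni-
#' adjust over the tests performed for that signature.
#'
#' @param variants Variant table (panel-filtered).
#' @param profiles Tumor profile table (`tumor_id`, `entity`, `sex`,
#'   `total_load`).
#' @param exposures Normalized exposure matrix (tumors x K).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @param signatures Character vector of signature names to scan
#'   (default: all columns of `exposures`).
#' @param mode Scan mode: `"normal"` (5\% entity positivity) or
#'   `"wide"` (2\%).
#' @param seed Integer seed (resampling reproducibility).
#' @param window_width,window_step,min_window_variants Scan geometry
#'   (defaults 2000/1000/6).
#' @param positivity_threshold Exposure positivity cutoff (default
#'   0.05).
#' @param resample_B,resample_max Resampling replicates and adaptive
#'   cap (defaults 999/99999; `resample_B = 0` disables calibration and
#'   adjusts raw p-values instead).
#' @param lambda_threshold Inflation-factor removal threshold (default
#'   1.5).
#' @param alpha Significance level applied to adjusted p-values
#'   (default 0.05).
#' @param perturb Compute per-site perturbation profiles for
#'   significant hotspots (default TRUE).
#' @return A `hotspot_scan` list: `results` (per-test table), `hotspots`
#'   (the hotspot objects), `lambda` (per-signature inflation report),
#'   `manifest` (thresholds, seed, m per signature).
#' @export
scan_cohort <- function(variants, profiles, exposures, chrom_sizes,
                        signatures = colnames(exposures),
                        mode = c("normal", "wide"), seed = 1L,
                        window_width = 2000L, window_step = 1000L,
                        min_window_variants = 6L,
                        positivity_threshold = 0.05,
                        resample_B = 999L, resample_max = 99999L,
                        lambda_threshold = 1.5, alpha = 0.05,
                        perturb = TRUE) {
  mode <- match.arg(mode)
  pos_m <- positivity(exposures, positivity_threshold)
  weights_all <- tumor_weight(pmax(profiles$total_load, 2L))
  names(weights_all) <- profiles$tumor_id
  loads_ok <- profiles$total_load
  res_rows <- list()
  hotspot_store <- list()
  m_per_sig <- stats::setNames(integer(length(signatures)), signatures)
  for (sig in signatures) {
    vsig <- restrict_entities(variants, pos_m, profiles, sig, mode = mode)
    if (!nrow(vsig)) next
    windows <- genome_scan_windows(vsig, chrom_sizes, width = window_width,
                                   step = window_step,
                                   min_variants = min_window_variants)
    if (!nrow(windows)) next
    tested <- list()
    keep_profiles <- profiles[profiles$tumor_id %in% unique(vsig$tumor_id) |
                                profiles$entity %in%
                                attr(vsig, "entities_kept"), ]
    null <- fit_null_model(exposures, keep_profiles, sig)
    wchrom <- windows$chrom; wstart <- windows$start; wend <- windows$end
    widx <- windows$variant_idx
    vs <- list(tumor_id = vsig$tumor_id, chrom = vsig$chrom, pos = vsig$pos,
               ref = vsig$ref, alt = vsig$alt)
    ## exact window prefilter: per chromosome, weighted prefix sums give
    ## every window's 30/15 bp sub-window load vector from two batched
    ## findInterval lookups; full pruning then runs only for windows
    ## whose load vector selects a hotspot sub-window (the prefilter
    ## computes the same L as bin_variants + weighted_load)
    candidate <- logical(nrow(windows))
    for (ch in unique(wchrom)) {
      ii <- which(vs$chrom == ch)
      o <- ii[order(vs$pos[ii])]
      pos_d <- as.double(vs$pos[o])
      cw <- c(0, cumsum(weights_all[vs$tumor_id[o]]))
      ww <- which(wchrom == ch)
      nsub_max <- max((wend[ww] - wstart[ww]) %/% 15L) + 1L
      offs <- seq.int(0L, by = 15L, length.out = nsub_max)
      S <- outer(offs, wstart[ww], `+`)             # nsub_max x n_windows
      endm <- rep(wend[ww], each = nsub_max)
      valid <- S <= endm
      E2 <- pmin(S + 29L, endm)
      L <- matrix(cw[findInterval(E2, pos_d) + 1L] -
                    cw[findInterval(S - 1L, pos_d) + 1L], nsub_max)
      L[!valid] <- 0
      nv <- colSums(valid)
      mu <- colSums(L) / nv
      sdv <- sqrt(pmax((colSums(L^2) - nv * mu^2) / pmax(nv - 1L, 1L), 0))
      sdv[nv == 1L] <- 0
      mx <- apply(ifelse(valid, L, -Inf), 2, max)
      ## slack absorbs float reordering; prune_region re-evaluates exactly
      tol <- 1e-9 * pmax(mx, 1)
      thr <- rep(pmax(mx / 2, mu + 3 * sdv) - tol, each = nsub_max)
      mu3 <- rep(3 * (mu - tol), each = nsub_max)
      candidate[ww] <- colSums(valid & L >= thr & L > mu3) > 0L
    }
    for (wi in which(candidate)) {
      idx <- widx[[wi]]
      vv <- list(
        tumor_id = vs$tumor_id[idx], chrom = vs$chrom[idx],
        pos = vs$pos[idx], ref = vs$ref[idx], alt = vs$alt[idx])
      hs <- prune_region(wchrom[wi], wstart[wi], wend[wi], vv, weights_all)
      if (is.null(hs) || !eligibility_check(hs)) next
      tested[[length(tested) + 1L]] <- list(hotspot = hs, window = wi)
    }
    m <- length(tested)
    m_per_sig[sig] <- m
    if (!m) next
    ## one permutation pool per signature scan, shared by all its tests
    perm_idx <- if (resample_B > 0)
      with_seed(seed + 7L, sample_perm_matrix(nrow(keep_profiles),
                                              resample_B))
    else NULL
    for (ti in seq_along(tested)) {
      hs <- tested[[ti]]$hotspot
      G <- genotype_matrix(hs, keep_profiles$tumor_id)
      sw <- variant_site_weights(hs, keep_profiles)
      test <- kernel_association_test(G, null, sw)
      p_res <- if (resample_B > 0) {
        rc <- resample_calibrate(test, B = resample_B, b_max = resample_max,
                                 seed = seed + ti, perm_idx = perm_idx)
        rc$p_resampled
      } else test$p_raw
      region_id <- paste0(hs$chrom, ":", hs$start, "-", hs$end)
      hotspot_store[[paste(sig, region_id)]] <-
        list(hotspot = hs, test = test, G = G, weights = sw, null = null)
      res_rows[[length(res_rows) + 1L]] <- data.table::data.table(
        region = region_id, chrom = hs$chrom, start = hs$start,
        end = hs$end, signature = sig, n_sites = test$n_sites,
        n_carriers = test$n_carriers,
        top_site = hs$sites$pos[which.max(hs$sites$R)],
        top_recurrence = max(hs$sites$R),
        p_raw = test$p_raw, p_resampled = p_res,
        direction = test$direction)
    }
  }
  results <- data.table::rbindlist(res_rows)
  lambda_report <- data.table::data.table(signature = signatures,
                                          m = as.integer(m_per_sig),
                                          lambda = NA_real_, flagged = FALSE)
  if (nrow(results)) {
    results[, p_adjusted := bonferroni_adjust(p_resampled,
                                              m_per_sig[signature]),
            by = signature]
    for (sig in unique(results$signature)) {
      ps <- results$p_resampled[results$signature == sig]
      if (length(ps) >= 10) {
        il <- inflation_lambda(ps, lambda_threshold)
        lambda_report[signature == sig,
                      `:=`(lambda = il$lambda, flagged = il$flagged)]
      }
    }
    results[, signature_flagged :=
              lambda_report$flagged[match(signature,
                                          lambda_report$signature)]]
    results[, significant := p_adjusted < alpha & !signature_flagged]
    ## per-site perturbation for significant hotspots
    results[, perturbation := ""]
    if (perturb && any(results$significant)) {
      for (ri in which(results$significant)) {
        key <- paste(results$signature[ri], results$region[ri])
        st <- hotspot_store[[key]]
        pp <- perturb_sites(st$test, st$G, st$null, st$weights)
        results$perturbation[ri] <- paste(
          sprintf("%s=%.3g", pp$site, pp$ratio), collapse = ";")
      }
    }
  }
  manifest <- list(
    seed = seed, mode = mode, signatures = signatures,
    thresholds = list(
      window_width = window_width, window_step = window_step,
      min_window_variants = min_window_variants,
      sub_window_width = 30L, sub_window_step = 15L,
      positivity_threshold = positivity_threshold,
      entity_positivity = if (mode == "normal") 0.05 else 0.02,
      eligibility_min_recurrence = 6L, eligibility_min_total = 10L,
      eligibility_min_recurrence_joint = 3L,
      resample_B = resample_B, resample_max = resample_max,
      lambda_threshold = lambda_threshold, alpha = alpha),
    m_per_signature = as.list(m_per_sig),
    package_version = as.character(utils::packageVersion("sighotspot")))
  structure(list(results = results, hotspots = hotspot_store,
                 lambda = lambda_report, manifest = manifest),
            class = "hotspot_scan")
}

#' @export
print.hotspot_scan <- function(x, ...) {
  cat("hotspot scan:", nrow(x$results), "eligible test(s) across",
      length(x$manifest$signatures), "signature(s)\n")
  if (nrow(x$results))
    cat("  significant:", sum(x$results$significant), "at alpha =",
        x$manifest$thresholds$alpha, "\n")
  invisible(x)
}

#' Annotate and classify scanned hotspots
#'
#' Applies chromatin-state, coding and driver annotation to each
#' significant hotspot's top site, runs the per-signature enrichment
#' tests (coding/regulatory permutation, known-driver hypergeometric)
#' with BH correction across the signature set, and emits driver calls.
#'
#' @param scan A `hotspot_scan` from [scan_cohort()].
#' @param tracks Annotation resources as produced by
#'   [simulate_annotation_tracks()] (fields `chromhmm`, `genes`, `cds`,
#'   `drivers`, `mappability`, `elements`), or equivalents read from
#'   BED/TSV files.
#' @param cgc_genes Character vector standing for Cancer Gene Census
#'   genes (defaults to `tracks$drivers`).
#' @param expression_effects Optional named logical vector per region id
#'   (criterion 3); absent regions count as unmet.
#' @param n_perm Permutation rounds for element enrichment (default
#'   1e5).
#' @param background_genes Hypergeometric background size (default
#'   21000).
#' @param seed Integer seed.
#' @param alpha Enrichment significance gate on q-values (default 0.05).
#' @return List with `annotations` (per-hotspot table), `enrichment`
#'   (per-signature table with q-values), `driver_calls` (per-hotspot
#'   classification).
#' @export
annotate_scan <- function(scan, tracks, cgc_genes = tracks$drivers,
                          expression_effects = NULL, n_perm = 100000L,
                          background_genes = 21000L, seed = 1L,
                          alpha = 0.05) {
  res <- scan$results
  if (!nrow(res) || !any(res$significant))
    return(list(annotations = data.table::data.table(),
                enrichment = data.table::data.table(),
                driver_calls = data.table::data.table()))
  sig_rows <- which(res$significant)
  ann <- data.table::rbindlist(lapply(sig_rows, function(ri) {
    ch <- res$chrom[ri]; p <- res$top_site[ri]
    cs <- annotate_chromhmm(ch, p, tracks$chromhmm)
    cd <- annotate_coding(ch, p, tracks$genes, tracks$cds)
    data.table::data.table(
      region = res$region[ri], signature = res$signature[ri],
      chrom = ch, top_site = p, top_recurrence = res$top_recurrence[ri],
      enhancer = cs$enhancer, tss = cs$tss, coding = cd$coding,
      nearest_gene = cd$nearest_gene,
      known_driver = !is.na(cd$nearest_gene) &&
        cd$nearest_gene %in% tracks$drivers,
      cgc_overlap = !is.na(cd$nearest_gene) && cd$nearest_gene %in% cgc_genes)
  }))
  ## per-signature enrichment
  sigs <- unique(ann$signature)
  enr <- data.table::rbindlist(lapply(sigs, function(sg) {
    a <- ann[ann$signature == sg, ]
    perm <- permutation_enrichment(
      data.frame(chrom = a$chrom, pos = a$top_site),
      tracks$elements, tracks$mappability, n_perm = n_perm, seed = seed)
    hyp <- hypergeometric_enrichment(
      stats::na.omit(unique(a$nearest_gene)), tracks$drivers,
      background = background_genes)
    data.table::data.table(
      signature = sg,
      p_elements = perm$p, observed_overlap = perm$observed,
      p_driver = hyp$p, driver_overlap = hyp$overlap,
      cgc_events = sum(a$cgc_overlap))
  }))
  enr[, q_elements := bh_adjust(p_elements)]
  enr[, q_driver := bh_adjust(p_driver)]
  enr[, driver_associated := mapply(
    classify_driver_associated_signature, q_driver, q_elements, cgc_events,
    MoreArgs = list(alpha = alpha))]
  calls <- data.table::rbindlist(lapply(seq_len(nrow(ann)), function(i) {
    da <- enr$driver_associated[match(ann$signature[i], enr$signature)]
    expr <- if (!is.null(expression_effects))
      unname(expression_effects[ann$region[i]]) else NA
    cl <- classify_putative_driver(ann$enhancer[i], ann$tss[i],
                                   ann$coding[i], expr,
                                   ann$top_recurrence[i], da)
    data.table::data.table(
      region = ann$region[i], signature = ann$signature[i],
      nearest_gene = ann$nearest_gene[i],
      signature_driver_associated = da,
      putative_driver = cl$putative_driver,
      criteria = paste(cl$criteria, collapse = ","))
  }))
  list(annotations = ann, enrichment = enr, driver_calls = calls)
}

#' Run the full discovery pipeline on a simulated or loaded cohort
#'
#' Thin composition used by the command-line interface: builds the
#' catalog, fits exposures, scans, annotates and writes result tables
#' plus a JSON manifest to `out_dir`.
#'
#' @param sim Cohort list as from [simulate_cohort()] (fields
#'   `variants`, `profiles`, `genome`, `signatures`).
#' @param out_dir Output directory.
#' @param tracks Optional annotation resources (see [annotate_scan()]);
#'   when `NULL` the annotation stage is skipped.
#' @param context_mode Catalog convention.
#' @param seed Integer seed.
#' @param ... Passed to [scan_cohort()].
#' @return The scan (invisibly), with annotation attached when run.
#' @export
run_scan <- function(sim, out_dir, tracks = NULL,
                     context_mode = c("trinucleotide", "nxsxn"),
                     seed = 1L, ...) {
  context_mode <- match.arg(context_mode)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- build_catalog(sim$variants, sim$genome, mode = context_mode,
                           tumors = sim$profiles$tumor_id)
  exposures <- fit_exposures(catalog, sim$signatures)
  chrom_sizes <- vapply(as_genome_strings(sim$genome), nchar, 0L)
  scan <- scan_cohort(sim$variants, sim$profiles, exposures, chrom_sizes,
                      seed = seed, ...)
  if (nrow(scan$results))
    data.table::fwrite(scan$results, file.path(out_dir, "associations.tsv"),
                       sep = "\t")
  else
    writeLines(paste("region", "chrom", "start", "end", "signature",
                     "n_sites", "n_carriers", "top_site", "top_recurrence",
                     "p_raw", "p_resampled", "direction", sep = "\t"),
               file.path(out_dir, "associations.tsv"))
  data.table::fwrite(scan$lambda, file.path(out_dir, "lambda_report.tsv"),
                     sep = "\t")
  if (!is.null(tracks)) {
    ann <- annotate_scan(scan, tracks, seed = seed)
    scan$annotation <- ann
    if (nrow(ann$annotations)) {
      data.table::fwrite(ann$annotations,
                         file.path(out_dir, "annotated_hotspots.tsv"),
                         sep = "\t")
      data.table::fwrite(ann$enrichment,
                         file.path(out_dir, "enrichment.tsv"), sep = "\t")
      data.table::fwrite(ann$driver_calls,
                         file.path(out_dir, "driver_calls.tsv"), sep = "\t")
    }
  }
  jsonlite::write_json(scan$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(scan)
}

#' Validate and load a YAML run configuration
#'
#' @param path YAML file with keys `variants`, `tumors`, `genome`,
#'   `signatures` (paths), optional `seed`, `mode`, `out`.
#' @return Named list; errors before any compute when a referenced path
#'   is missing.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in c("variants", "tumors", "genome", "signatures")) {
    if (is.null(cfg[[key]])) stop("config missing key: ", key)
    if (!file.exists(cfg[[key]]))
      stop("config path for '", key, "' does not exist: ", cfg[[key]])
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$mode)) cfg$mode <- "normal"
  if (is.null(cfg$out)) cfg$out <- "sighotspot_out"
  cfg
}

#' Load a cohort from the files referenced by a run configuration
#'
#' @param cfg List from [load_run_config()].
#' @return Cohort list as consumed by [run_scan()].
#' @export
load_cohort <- function(cfg) {
  variants <- read_variant_table(cfg$variants)
  metadata <- data.table::fread(cfg$tumors, sep = "\t")
  genome <- Biostrings::readDNAStringSet(cfg$genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  signatures <- read_signature_matrix(cfg$signatures)
  if (!is.null(cfg$panel)) {
    panel <- read_panel_of_normals(cfg$panel)
    variants <- filter_panel_artifacts(variants, panel)
  }
  profiles <- compute_tumor_loads(variants, as.data.frame(metadata))
  list(variants = variants, profiles = profiles,
       genome = as_genome_strings(genome), signatures = signatures)
}
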