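## Seeded synthetic tumor cohorts with ground truth.
##
## The simulator emulates the ingredients the pipeline consumes: a
## synthetic reference contig, per-tumor signature exposures (Dirichlet
## per entity), genome-wide mutational loads (truncated log-normal),
## background mutations drawn from the exposure-mixed signature profiles
## and placed at context-matching positions, and planted hotspots whose
## carriers get a shared substitution plus an exposure shift on the
## target signature.  Everything is keyed to a mandatory integer seed.

#' Build a simulation configuration
#'
#' @param n_tumors Cohort size (default 300).
#' @param entities Named numeric vector of entity proportions (must sum
#'   to 1).
#' @param signatures Signature matrix K x 96; default: a 5-signature
#'   synthetic set derived from the seed.
#' @param dirichlet_alpha Base Dirichlet concentration over signatures;
#'   each entity uses a rotation of this vector so entities differ in
#'   signature activity (default `c(6, 5, 4, 3, 2)` recycled to K).
#' @param load_meanlog,load_sdlog Log-normal parameters of the per-tumor
#'   genome-wide mutational load (defaults `log(2000)` and 1).
#' @param load_range Truncation bounds for the load (default
#'   `c(50, 1e5)`).
#' @param genome_length Length in bp of the synthetic contig `chrS`
#'   (default 5e6; at the default load this balances a workable per-bp
#'   density against the collision-driven background recurrence that
#'   grows as the contig shrinks).
#' @param hotspots `data.frame` of planted hotspots with columns
#'   `position`, `signature` (name), `effect_size` (exposure shift in
#'   units of the within-entity exposure SD), `carrier_fraction`.
#'   `NULL` for none.
#' @param context_mode Catalog convention for downstream use.
#' @param seed Mandatory integer seed.
#' @param genome_seed Seed of the synthetic reference contig (default
#'   `seed + 2`); cohorts sharing a `genome_seed` share one reference,
#'   as real cohorts do, and the contig is cached across simulations.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_tumors = 300L,
                          entities = c(entA = 0.5, entB = 0.3, entC = 0.2),
                          signatures = NULL,
                          dirichlet_alpha = NULL,
                          load_meanlog = log(2000), load_sdlog = 1,
                          load_range = c(50, 1e5),
                          genome_length = 5e6,
                          hotspots = NULL,
                          context_mode = c("trinucleotide", "nxsxn"),
                          seed, genome_seed = NULL) {
  if (missing(seed)) stop("a seed is mandatory for cohort simulation")
  context_mode <- match.arg(context_mode)
  if (abs(sum(entities) - 1) > 1e-8) stop("entity proportions must sum to 1")
  if (is.null(signatures))
    signatures <- make_synthetic_signatures(5, seed = seed + 1000L)
  k <- nrow(signatures)
  if (is.null(dirichlet_alpha))
    dirichlet_alpha <- rep_len(c(6, 5, 4, 3, 2), k)
  if (!is.null(hotspots)) {
    need <- c("position", "signature", "effect_size", "carrier_fraction")
    if (!all(need %in% names(hotspots)))
      stop("hotspots needs columns: ", paste(need, collapse = ", "))
    stopifnot(all(is.finite(hotspots$effect_size)),
              all(hotspots$signature %in% rownames(signatures)))
  }
  structure(list(n_tumors = as.integer(n_tumors), entities = entities,
                 signatures = signatures, dirichlet_alpha = dirichlet_alpha,
                 load_meanlog = load_meanlog, load_sdlog = load_sdlog,
                 load_range = load_range,
                 genome_length = as.integer(genome_length),
                 hotspots = hotspots, context_mode = context_mode,
                 seed = as.integer(seed),
                 genome_seed = as.integer(if (is.null(genome_seed))
                   seed + 2L else genome_seed)),
            class = "cohort_config")
}

#' Simulate a synthetic tumor cohort
#'
#' Per tumor: draw an entity, an exposure vector from the entity's
#' Dirichlet, and a load V_t; shift the target-signature exposure of
#' planted-hotspot carriers by `effect_size` within-entity SDs
#' (reallocating mass from the other signatures); then draw V_t context
#' classes from the exposure-mixed signature profiles and place them
#' uniformly among context-matching positions of the synthetic contig.
#' Planted carriers additionally receive a shared substitution at the
#' hotspot site.
#'
#' @param cfg A [cohort_config()].
#' @return List with `variants` (variant table), `profiles` (tumor
#'   metadata + loads), `exposures_true`, `genome` (named character),
#'   `signatures`, and `truth` (planted hotspot manifest with carriers).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  with_seed(cfg$seed, simulate_cohort_impl(cfg))
}

#' Simulate a matched null cohort
#'
#' Identical generative process with all planted effect sizes forced to
#' 0: carriers still share the hotspot substitutions (so regions remain
#' testable) but their exposures are not shifted, removing any
#' hotspot-exposure coupling.
#'
#' @param cfg A [cohort_config()].
#' @return As [simulate_cohort()]; the truth manifest records effect 0.
#' @export
simulate_null_cohort <- function(cfg) {
  if (!is.null(cfg$hotspots)) cfg$hotspots$effect_size <- 0
  simulate_cohort(cfg)
}

simulate_cohort_impl <- function(cfg) {
  S <- cfg$signatures
  k <- nrow(S)
  n <- cfg$n_tumors

  ## synthetic contig (i.i.d. uniform A/C/G/T) plus its context-position
  ## index, keyed by genome_seed and cached across simulations
  gres <- cached_synthetic_genome(cfg$genome_seed, cfg$genome_length,
                                  cfg$context_mode)
  genome_chars <- gres$chars
  genome <- list(chrS = gres$str)
  ctx_index <- gres$ctx_index

  ## tumors
  tumor_id <- sprintf("T%04d", seq_len(n))
  entity <- sample(names(cfg$entities), n, replace = TRUE,
                   prob = cfg$entities)
  sex <- sample(c("female", "male"), n, replace = TRUE)

  ## per-entity Dirichlet (rotated alpha so entities differ)
  alpha_by_entity <- lapply(seq_along(cfg$entities), function(i)
    cfg$dirichlet_alpha[((seq_len(k) + i - 2L) %% k) + 1L])
  names(alpha_by_entity) <- names(cfg$entities)
  E <- matrix(0, n, k, dimnames = list(tumor_id, rownames(S)))
  for (ent in names(cfg$entities)) {
    idx <- which(entity == ent)
    if (length(idx)) E[idx, ] <- rdirichlet(length(idx), alpha_by_entity[[ent]])
  }

  ## within-entity exposure SD per signature (pooled), the unit of the
  ## planted effect sizes
  sd_within <- vapply(seq_len(k), function(j) {
    v <- tapply(E[, j], entity, stats::var)
    sqrt(stats::weighted.mean(v[!is.na(v)],
                              table(entity)[names(v)[!is.na(v)]]))
  }, numeric(1))

  ## planted hotspots: carriers and exposure shifts
  truth <- NULL
  hs <- cfg$hotspots
  if (!is.null(hs) && nrow(hs)) {
    truth <- vector("list", nrow(hs))
    for (h in seq_len(nrow(hs))) {
      sig <- hs$signature[h]
      j <- match(sig, rownames(S))
      n_car <- max(1L, round(hs$carrier_fraction[h] * n))
      carriers <- sample(tumor_id, n_car)
      delta <- hs$effect_size[h] * sd_within[j]
      if (delta != 0) {
        ci <- match(carriers, tumor_id)
        e_new <- pmin(E[ci, j] + delta, 0.95)
        scale <- (1 - e_new) / pmax(1 - E[ci, j], 1e-12)
        E[ci, ] <- E[ci, ] * scale
        E[ci, j] <- e_new
        E[ci, ] <- E[ci, ] / rowSums(E[ci, , drop = FALSE])
      }
      ## site class: the target signature's dominant context class;
      ## site position: nearest context-matching position
      cls <- which.max(S[j, ])
      site_pos <- nearest_class_position(ctx_index, cls, hs$position[h])
      if (is.na(site_pos))
        stop("genome too short to host the requested hotspot context")
      truth[[h]] <- list(chrom = "chrS", pos = site_pos, class = cls,
                         signature = sig, effect_size = hs$effect_size[h],
                         carriers = carriers)
    }
  }

  ## genome-wide loads
  V <- round(stats::rlnorm(n, cfg$load_meanlog, cfg$load_sdlog))
  V <- pmin(pmax(V, cfg$load_range[1]), cfg$load_range[2])

  ## background mutations: classes per tumor from the exposure mix,
  ## positions per class from the context index
  P <- E %*% S                                  # n x 96 class probabilities
  cls_counts <- matrix(0L, n, 96L)
  for (i in seq_len(n))
    cls_counts[i, ] <- stats::rmultinom(1, V[i], P[i, ])
  tum_idx <- rep(seq_len(n), times = V)
  cls_all <- unlist(lapply(seq_len(n), function(i)
    rep.int(seq_len(96L), cls_counts[i, ])), use.names = FALSE)
  pos_all <- integer(length(cls_all))
  ref_all <- character(length(cls_all))
  alt_all <- character(length(cls_all))
  for (c96 in sort(unique(cls_all))) {
    sel <- which(cls_all == c96)
    pool <- ctx_index$positions[[ctx_index$class_to_pool[c96]]]
    if (!length(pool))
      stop("genome too short: no position matches context class ", c96)
    pos_all[sel] <- pool[sample.int(length(pool), length(sel), replace = TRUE)]
  }
  ref_all <- genome_chars[pos_all]
  alt_all <- class_alt_on_genome(cls_all, ref_all)

  v <- data.table::data.table(tumor_id = tumor_id[tum_idx], chrom = "chrS",
                              pos = pos_all, ref = ref_all, alt = alt_all)

  ## planted site variants
  if (!is.null(truth)) {
    extra <- data.table::rbindlist(lapply(truth, function(t) {
      refb <- genome_chars[t$pos]
      data.table::data.table(tumor_id = t$carriers, chrom = t$chrom,
                             pos = t$pos, ref = refb,
                             alt = class_alt_on_genome(rep(t$class,
                               length(t$carriers)), rep(refb,
                               length(t$carriers))))
    }))
    v <- rbind(v, extra)
  }
  ## one substitution per tumor and position (fromLast keeps planted
  ## sites, appended after the background draws); this also enforces
  ## (tumor, chrom, pos, alt) uniqueness
  v <- v[!duplicated(v, by = c("tumor_id", "chrom", "pos"), fromLast = TRUE)]
  data.table::setorderv(v, c("chrom", "pos", "tumor_id", "alt"))

  metadata <- data.frame(tumor_id = tumor_id, entity = entity, sex = sex,
                         stringsAsFactors = FALSE)
  profiles <- compute_tumor_loads(v, metadata)

  ## re-attach truth carriers surviving deduplication (all, in practice)
  if (!is.null(truth)) {
    site_key <- paste0(vapply(truth, function(t) t$chrom, ""), ":",
                       vapply(truth, function(t) t$pos, 0L), ":",
                       vapply(truth, function(t) class_alt_on_genome(
                         t$class, genome_chars[t$pos]), ""))
    vhit <- which(v$pos %in% vapply(truth, function(t) t$pos, 0L))
    vkey <- paste0(v$chrom[vhit], ":", v$pos[vhit], ":", v$alt[vhit])
    for (h in seq_along(truth)) {
      t <- truth[[h]]
      truth[[h]]$alt <- sub("^.*:", "", site_key[h])
      obs_tum <- v$tumor_id[vhit[vkey == site_key[h]]]
      truth[[h]]$carriers_observed <- intersect(obs_tum, t$carriers)
    }
  }

  list(variants = v, profiles = profiles, exposures_true = E,
       genome = genome, signatures = S,
       truth = list(hotspots = truth, seed = cfg$seed,
                    sd_within = stats::setNames(sd_within, rownames(S))))
}

## One-slot cache of the synthetic contig and its context index.
.genome_cache <- new.env(parent = emptyenv())

cached_synthetic_genome <- function(genome_seed, genome_length, mode) {
  key <- paste(genome_seed, genome_length, mode)
  if (identical(.genome_cache$key, key)) return(.genome_cache$value)
  value <- with_seed(genome_seed, {
    chars <- sample(.BASES, genome_length, replace = TRUE)
    list(chars = chars, str = paste(chars, collapse = ""),
         ctx_index = context_position_index(chars, mode))
  })
  .genome_cache$key <- key
  .genome_cache$value <- value
  value
}

## Index of genome positions by the pyrimidine-strand context class pool
## they can host.  Pools are keyed by (pyrimidine center C/T, 5' flank,
## 3' flank) after strand normalization -- 32 pools; each of the 96
## classes maps to the pool of its (center, flanks).
context_position_index <- function(genome_chars, mode) {
  off <- if (mode == "trinucleotide") 1L else 2L
  len <- length(genome_chars)
  pos <- (off + 1L):(len - off)
  code <- match(genome_chars, .BASES)           # A=1 C=2 G=3 T=4
  center <- code[pos]
  up <- code[pos - off]
  dn <- code[pos + off]
  flip <- center == 1L | center == 3L           # purine centers
  comp <- 5L - center
  pyr <- ifelse(flip, comp, center)             # 2 (C) or 4 (T)
  f5 <- up; f5[flip] <- 5L - dn[flip]
  f3 <- dn; f3[flip] <- 5L - up[flip]
  pool_id <- (pyr %/% 2L - 1L) * 16L + (f5 - 1L) * 4L + f3   # 1..32
  positions <- split(pos, factor(pool_id, levels = 1:32))
  ## class -> pool: class index (sub, f5, f3); sub 1-3 are C>, 4-6 are T>
  grid <- expand.grid(f3 = 1:4, f5 = 1:4, sub = 1:6)
  class_to_pool <- (ifelse(grid$sub <= 3, 0L, 1L)) * 16L +
    (grid$f5 - 1L) * 4L + grid$f3
  list(positions = positions, class_to_pool = class_to_pool,
       flip_at = flip, pos_range = range(pos))
}

## Alternate allele of a class realised at a genome position: classes
## are defined on the pyrimidine strand; if the genome base is a purine
## the substitution is complemented back to the genome strand.
class_alt_on_genome <- function(cls, genome_ref) {
  sub_i <- (cls - 1L) %/% 16L + 1L           # 1..6
  alt_pyr <- c("A", "G", "T", "A", "C", "G")[sub_i]
  ifelse(genome_ref %in% c("A", "G"), .revcomp_base(alt_pyr), alt_pyr)
}

## Nearest position (to `target`) whose context pool matches class `cls`.
## Pools are sorted, so a binary search suffices.
nearest_class_position <- function(ctx_index, cls, target) {
  pool <- ctx_index$positions[[ctx_index$class_to_pool[cls]]]
  if (!length(pool)) return(NA_integer_)
  i <- findInterval(target, pool)
  cand <- pool[unique(pmin(pmax(c(i, i + 1L), 1L), length(pool)))]
  cand[which.min(abs(cand - target))]
}

#' Write a simulated cohort to disk
#'
#' Emits the same plain-text formats the pipeline consumes: MAF-like
#' variant TSV, tumor metadata TSV, reference FASTA, signature TSV, true
#' exposure TSV, and a JSON truth manifest.
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_variant_table(sim$variants, file.path(dir, "variants.tsv"))
  data.table::fwrite(sim$profiles, file.path(dir, "tumors.tsv"), sep = "\t")
  writeLines(c(">chrS", chunk_string(sim$genome$chrS, 80L)),
             file.path(dir, "genome.fa"))
  write_signature_matrix(sim$signatures, file.path(dir, "signatures.tsv"))
  write_exposures(sim$exposures_true, file.path(dir, "exposures_true.tsv"))
  truth <- sim$truth
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

chunk_string <- function(s, width) {
  n <- nchar(s)
  starts <- seq(1L, n, width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Generate synthetic annotation resources for a simulated genome
#'
#' Small ChromHMM-style chromatin tracks, a gene model, a known-driver
#' list and a mappability table matched to the synthetic contig, so the
#' annotation stage can run end-to-end on simulated data.  These are
#' synthetic stand-ins, not biological annotations.
#'
#' @param cfg A [cohort_config()].
#' @param n_epigenomes Number of chromatin tracks (default 12).
#' @param n_genes Number of synthetic genes (default 40).
#' @return List with `chromhmm` (list of data.frames), `genes`
#'   (data.frame gene model), `drivers` (character vector),
#'   `mappability` (data.frame), `elements` (coding+regulatory
#'   intervals).
#' @export
simulate_annotation_tracks <- function(cfg, n_epigenomes = 12L,
                                       n_genes = 40L) {
  with_seed(cfg$seed + 2000L, {
    glen <- cfg$genome_length
    states <- chromhmm_state_names()
    chromhmm <- lapply(seq_len(n_epigenomes), function(e) {
      brk <- sort(c(0L, sample.int(glen - 1L, 199L), glen))
      data.frame(chrom = "chrS", start = brk[-length(brk)], end = brk[-1],
                 state = sample(states, length(brk) - 1L, replace = TRUE,
                                prob = c(rep(2, 2), rep(1, 16))),
                 stringsAsFactors = FALSE)
    })
    gstart <- sort(sample.int(glen - 6000L, n_genes))
    genes <- data.frame(chrom = "chrS", start = gstart,
                        end = gstart + 4999L,
                        gene = sprintf("GENE%03d", seq_len(n_genes)),
                        stringsAsFactors = FALSE)
    cds <- data.frame(chrom = "chrS", start = genes$start + 1000L,
                      end = genes$start + 2999L, gene = genes$gene,
                      stringsAsFactors = FALSE)
    drivers <- sample(genes$gene, max(3L, n_genes %/% 4L))
    mappability <- data.frame(chrom = "chrS", start = 0L, end = glen,
                              score = 1, stringsAsFactors = FALSE)
    elements <- rbind(
      data.frame(chrom = "chrS", start = cds$start, end = cds$end,
                 type = "coding", stringsAsFactors = FALSE),
      data.frame(chrom = "chrS", start = pmax(genes$start - 1500L, 0L),
                 end = genes$start, type = "regulatory",
                 stringsAsFactors = FALSE))
    list(chromhmm = chromhmm, genes = genes, cds = cds, drivers = drivers,
         mappability = mappability, elements = elements)
  })
}
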