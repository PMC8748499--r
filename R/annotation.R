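## Knowledge-based annotation of hotspots and enrichment tests.
##
## Chromatin-state annotation follows the 18-state ChromHMM vocabulary:
## a hotspot's top site is intersected with every epigenome; the ratio
## of epigenomes in enhancer states (EnhG1, EnhG2, EnhA1, EnhA2) to
## epigenomes in the enhancer background states (states 1-6, 12-14)
## must exceed 1:2 for an enhancer call, and analogously for TSS states
## (TssA, TssFlnk) against the TSS background (states 5-6, 7-15).

#' 18-state ChromHMM vocabulary
#'
#' State names in model order (1 TssA ... 18 Quies).
#'
#' @return Character vector of length 18.
#' @export
chromhmm_state_names <- function() {
  c("TssA", "TssFlnk", "TssFlnkU", "TssFlnkD", "Tx", "TxWk", "EnhG1",
    "EnhG2", "EnhA1", "EnhA2", "EnhWk", "ZNF/Rpts", "Het", "TssBiv",
    "EnhBiv", "ReprPC", "ReprPCWk", "Quies")
}

.ENH_STATES <- c("EnhG1", "EnhG2", "EnhA1", "EnhA2")
.ENH_BACKGROUND <- chromhmm_state_names()[c(1:6, 12:14)]
.TSS_STATES <- c("TssA", "TssFlnk")
.TSS_BACKGROUND <- chromhmm_state_names()[c(5:6, 7:15)]

#' Read ChromHMM segmentation BED files
#'
#' One 4-column BED per epigenome (chrom, start, end, state label;
#' 0-based half-open, converted to 1-based inclusive internally).
#'
#' @param paths Character vector of BED paths.
#' @return List of data.frames (`chrom`, `start`, `end` 1-based
#'   inclusive, `state`).
#' @export
read_chromhmm_beds <- function(paths) {
  lapply(paths, function(p) {
    b <- data.table::fread(p, header = FALSE,
                           col.names = c("chrom", "start", "end", "state"))
    data.frame(chrom = as.character(b$chrom), start = b$start + 1L,
               end = as.integer(b$end), state = as.character(b$state),
               stringsAsFactors = FALSE)
  })
}

## State of one epigenome at a 1-based position (NA when uncovered).
## Accepts 0-based half-open (start < end, as read_chromhmm... already
## converts) data.frames with 1-based inclusive start/end.
state_at <- function(track, chrom, pos) {
  hit <- track$chrom == chrom & track$start <= pos & track$end >= pos
  if (!any(hit)) NA_character_ else track$state[which(hit)[1]]
}

#' Chromatin-state annotation of a hotspot site
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param tracks List of per-epigenome segmentations (see
#'   [read_chromhmm_beds()] or [simulate_annotation_tracks()]).
#' @param enh_states,enh_background,tss_states,tss_background State
#'   sets; defaults follow the 18-state convention described in the
#'   file header.
#' @return List with logical `enhancer`, `tss` and the epigenome counts.
#'   A site with background count 0 but a positive state count is
#'   flagged TRUE (unbounded ratio); a site outside every track gets
#'   both flags FALSE.
#' @export
annotate_chromhmm <- function(chrom, pos, tracks,
                              enh_states = .ENH_STATES,
                              enh_background = .ENH_BACKGROUND,
                              tss_states = .TSS_STATES,
                              tss_background = .TSS_BACKGROUND) {
  stopifnot(length(tracks) >= 1)
  states <- vapply(tracks, state_at, "", chrom = chrom, pos = pos)
  states <- states[!is.na(states)]
  ratio_flag <- function(hits, bg) {
    e <- sum(states %in% hits); b <- sum(states %in% bg)
    flag <- if (b == 0) e > 0 else (e / b) > 0.5
    list(flag = flag, n_state = e, n_background = b)
  }
  enh <- ratio_flag(enh_states, enh_background)
  tss <- ratio_flag(tss_states, tss_background)
  list(enhancer = enh$flag, tss = tss$flag,
       counts = c(enhancer = enh$n_state, enhancer_bg = enh$n_background,
                  tss = tss$n_state, tss_bg = tss$n_background,
                  covered = length(states)))
}

#' Coding status and nearest gene of a hotspot site
#'
#' @param chrom,pos Site coordinates (1-based).
#' @param genes Gene model data.frame (`chrom`, `start`, `end`, `gene`;
#'   1-based inclusive).
#' @param cds CDS intervals in the same format (may be `NULL`: coding
#'   flag then FALSE).
#' @return List with `coding` flag and `nearest_gene` (alphabetically
#'   first on distance ties, tie noted via attribute; `NA` for an empty
#'   gene model).
#' @export
annotate_coding <- function(chrom, pos, genes, cds = NULL) {
  coding <- FALSE
  if (!is.null(cds) && nrow(cds))
    coding <- any(cds$chrom == chrom & cds$start <= pos & cds$end >= pos)
  if (is.null(genes) || !nrow(genes))
    return(list(coding = coding, nearest_gene = NA_character_))
  g <- genes[genes$chrom == chrom, ]
  if (!nrow(g)) return(list(coding = coding, nearest_gene = NA_character_))
  dist <- pmax(g$start - pos, pos - g$end, 0L)
  nearest <- sort(g$gene[dist == min(dist)])
  if (length(nearest) > 1)
    message("nearest-gene tie at ", chrom, ":", pos, " resolved to ",
            nearest[1])
  list(coding = coding, nearest_gene = nearest[1],
       distance = min(dist))
}

#' Permutation enrichment of hotspot sites in genomic elements
#'
#' Draws `n_perm` random site sets of the observed size uniformly over
#' the mappable genome (intervals with mappability >= `min_mappability`)
#' and compares element-overlap counts:
#' `p = (1 + #\{permutation >= observed\}) / (n_perm + 1)`, one-sided.
#'
#' @param sites data.frame of hotspot top sites (`chrom`, `pos`).
#' @param elements data.frame of element intervals (`chrom`, `start`,
#'   `end`, 0-based half-open as in BED).
#' @param mappability data.frame (`chrom`, `start`, `end`, `score`,
#'   0-based half-open).
#' @param n_perm Permutation rounds (default 1e5).
#' @param min_mappability Minimum retained mappability (default 0.25).
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `n_perm`, and the permutation
#'   overlap distribution summary.
#' @export
permutation_enrichment <- function(sites, elements, mappability,
                                   n_perm = 100000L, min_mappability = 0.25,
                                   seed = 1L) {
  map <- mappability[mappability$score >= min_mappability, , drop = FALSE]
  if (!nrow(map)) stop("no mappable territory at this threshold")
  map_gr <- GenomicRanges::GRanges(map$chrom,
    IRanges::IRanges(map$start + 1L, map$end))
  map_gr <- GenomicRanges::reduce(map_gr)
  ele_gr <- GenomicRanges::GRanges(elements$chrom,
    IRanges::IRanges(elements$start + 1L, elements$end))
  ## project elements onto the concatenated mappable coordinate line
  inter <- GenomicRanges::intersect(ele_gr, map_gr)
  w <- GenomicRanges::width(map_gr)
  offset <- cumsum(c(0, as.numeric(w[-length(w)])))
  total <- sum(as.numeric(w))
  hit <- GenomicRanges::findOverlaps(inter, map_gr)
  ele_lin <- if (length(hit)) {
    qs <- GenomicRanges::start(inter)[S4Vectors::queryHits(hit)]
    qe <- GenomicRanges::end(inter)[S4Vectors::queryHits(hit)]
    ms <- GenomicRanges::start(map_gr)[S4Vectors::subjectHits(hit)]
    off <- offset[S4Vectors::subjectHits(hit)]
    cbind(off + pmax(qs, ms) - ms + 1, off + qe - ms + 1)
  } else matrix(numeric(0), 0, 2)
  in_elements <- function(lin_pos) {
    if (!nrow(ele_lin)) return(rep(FALSE, length(lin_pos)))
    i <- findInterval(lin_pos, ele_lin[, 1])
    i > 0 & lin_pos <= ele_lin[pmax(i, 1), 2]
  }
  if (nrow(ele_lin) > 1) {
    o <- order(ele_lin[, 1]); ele_lin <- ele_lin[o, , drop = FALSE]
  }
  ## observed overlap (in genome coordinates)
  site_gr <- GenomicRanges::GRanges(sites$chrom,
    IRanges::IRanges(sites$pos, sites$pos))
  observed <- sum(IRanges::overlapsAny(site_gr, ele_gr))
  h <- nrow(sites)
  with_seed(seed, {
    draws <- matrix(ceiling(stats::runif(n_perm * h) * total), n_perm, h)
    hits <- matrix(in_elements(as.vector(draws)), n_perm, h)
    perm_overlap <- rowSums(hits)
  })
  p <- (1 + sum(perm_overlap >= observed)) / (n_perm + 1)
  list(p = p, observed = observed, n_perm = n_perm,
       perm_mean = mean(perm_overlap), mappable_bp = total)
}

#' Hypergeometric enrichment of hit genes in a target set
#'
#' Upper-tail hypergeometric probability `P(X >= overlap)` of drawing
#' `length(hits)` genes from a background of `background` genes of which
#' `length(targets)` are targets.
#'
#' @param hits Character vector of hit genes.
#' @param targets Character vector of target genes (e.g. known drivers).
#' @param background Background universe size (default 21000 coding
#'   genes).
#' @return List with `p`, `overlap`, `K`, `n`, `N`.
#' @export
hypergeometric_enrichment <- function(hits, targets, background = 21000L) {
  hits <- unique(hits); targets <- unique(targets)
  K <- length(targets); n <- length(hits)
  overlap <- length(intersect(hits, targets))
  if (K > background || n > background)
    stop("sets larger than the background universe")
  p <- stats::phyper(overlap - 1L, K, background - K, n, lower.tail = FALSE)
  list(p = p, overlap = overlap, K = K, n = n, N = background)
}

#' Benjamini-Hochberg adjustment across a signature set
#'
#' Step-up false discovery rate with monotonicity enforcement
#' (delegates to [stats::p.adjust()]).
#'
#' @param p P-values.
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Classify a signature as driver-associated
#'
#' A mutational signature is driver-associated when its hotspots are
#' significantly enriched in known drivers AND in coding/regulatory
#' elements (both q below `alpha`), with strictly more than
#' `min_cgc_events` events overlapping Cancer Gene Census genes.
#'
#' @param q_driver Known-driver enrichment q-value.
#' @param q_elements Coding/regulatory permutation q-value.
#' @param cgc_overlap Count of events overlapping CGC genes.
#' @param alpha Significance gate (default 0.05).
#' @param min_cgc_events Strict lower bound (default 3, i.e. "more than
#'   three").
#' @return Logical.
#' @export
classify_driver_associated_signature <- function(q_driver, q_elements,
                                                 cgc_overlap, alpha = 0.05,
                                                 min_cgc_events = 3L) {
  isTRUE(q_driver < alpha) && isTRUE(q_elements < alpha) &&
    isTRUE(cgc_overlap > min_cgc_events)
}

#' Classify a significant hotspot as a putative driver
#'
#' A hotspot (already significant after multiple-testing correction) is
#' a putative driver when its signature is driver-associated AND it
#' meets at least one of: (1) lies in a regulatory element (enhancer or
#' TSS), (2) lies in a coding region, (3) affects expression, (4) is
#' highly recurrent (top-site recurrence >= `min_recurrence`).
#' Hotspots of non-driver-associated signatures are susceptible targets,
#' never putative drivers.
#'
#' @param enhancer,tss,coding Logical annotation flags.
#' @param expression_effect Optional logical (externally supplied
#'   differential-expression evidence); `NA`/`NULL` means criterion 3
#'   is unmet.
#' @param top_recurrence Recurrence of the hotspot's top site.
#' @param signature_driver_associated Logical gate from
#'   [classify_driver_associated_signature()].
#' @param min_recurrence Recurrence criterion threshold (default 10).
#' @return List with `putative_driver` and the `criteria` met (subset of
#'   regulatory/coding/expression/recurrence).
#' @export
classify_putative_driver <- function(enhancer, tss, coding,
                                     expression_effect = NULL,
                                     top_recurrence,
                                     signature_driver_associated,
                                     min_recurrence = 10L) {
  crit <- c(
    regulatory = isTRUE(enhancer) || isTRUE(tss),
    coding = isTRUE(coding),
    expression = isTRUE(expression_effect),
    recurrence = isTRUE(top_recurrence >= min_recurrence))
  list(putative_driver = isTRUE(signature_driver_associated) && any(crit),
       criteria = names(crit)[crit])
}
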