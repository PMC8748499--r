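## Genomic window scan and hotspot pruning.
##
## The scan tiles each chromosome with half-overlapping 2 kb windows
## (step 1 kb); windows holding fewer than 6 variants are discarded.
## Within a candidate window, variants are binned into 30 bp sub-windows
## at 15 bp steps, each tumor contributes with weight 1/log2(V_t), and a
## sub-window i with weighted load L_i is selected as a hotspot when
##   L_i >= max(L)/2   and   L_i > 3*mean(L)   and   L_i >= mean(L)+3*sd(L)
## (sample standard deviation, n-1 denominator).

#' Per-tumor pruning weight
#'
#' `w_t = 1 / log2(V_t)` where `V_t` is the tumor's total somatic SNV
#' load.  Loads below 2 are clamped to 2 with a warning (log2(1) = 0
#' would divide by zero).
#'
#' @param total_load Integer vector of per-tumor loads.
#' @return Numeric vector of weights.
#' @export
tumor_weight <- function(total_load) {
  if (any(total_load < 2)) {
    warning("tumor load(s) < 2 clamped to 2 for weighting")
    total_load <- pmax(total_load, 2)
  }
  1 / log2(total_load)
}

#' Restrict variants to entities relevant for a signature
#'
#' Keeps only variants from tumors whose entity has a fraction of
#' signature-positive tumors of at least 5\% (normal mode) or 2\%
#' (wide mode).
#'
#' @param v Variant table.
#' @param pos_matrix Logical positivity matrix (tumors x signatures,
#'   see [positivity()]).
#' @param profiles Tumor profile table (`tumor_id`, `entity`, ...).
#' @param signature Signature name (column of `pos_matrix`).
#' @param mode `"normal"` (threshold 0.05) or `"wide"` (0.02).
#' @return The restricted variant table; attribute `entities_kept` lists
#'   the retained entities.
#' @export
restrict_entities <- function(v, pos_matrix, profiles, signature,
                              mode = c("normal", "wide")) {
  mode <- match.arg(mode)
  thr <- if (mode == "normal") 0.05 else 0.02
  if (!signature %in% colnames(pos_matrix))
    stop("signature '", signature, "' not in positivity matrix")
  posv <- pos_matrix[match(profiles$tumor_id, rownames(pos_matrix)), signature]
  frac <- tapply(posv, profiles$entity, mean)
  keep_ent <- names(frac)[!is.na(frac) & frac >= thr]
  keep_tum <- profiles$tumor_id[profiles$entity %in% keep_ent]
  out <- v[v$tumor_id %in% keep_tum, ]
  data.table::setattr(out, "entities_kept", keep_ent)
  out
}

#' Tile the genome with candidate scan windows
#'
#' Half-overlapping windows of `width` bp at `step` bp, tiled from
#' coordinate 1 per chromosome (the final window is truncated at the
#' chromosome end and retained if it meets `min_variants`).  Windows with
#' fewer than `min_variants` variant records are discarded.
#'
#' @param v Variant table (positions 1-based).
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @param width,step Window geometry in bp (defaults 2000/1000).
#' @param min_variants Minimum records per retained window (default 6;
#'   a window with exactly `min_variants` records is retained).
#' @return `data.table` with columns `chrom`, `start`, `end`,
#'   `n_variants` and a list column `variant_idx` of row indices into `v`.
#' @export
genome_scan_windows <- function(v, chrom_sizes, width = 2000L, step = 1000L,
                                min_variants = 6L) {
  miss <- setdiff(unique(v$chrom), names(chrom_sizes))
  if (length(miss))
    stop("chrom_sizes missing chromosome(s): ", paste(miss, collapse = ", "))
  res <- vector("list", length(chrom_sizes))
  for (ci in seq_along(chrom_sizes)) {
    ch <- names(chrom_sizes)[ci]
    size <- chrom_sizes[[ci]]
    starts <- if (size <= width) 1L else seq.int(1L, max(1L, size - step), step)
    ends <- pmin(starts + width - 1L, size)
    idx <- which(v$chrom == ch)
    p <- v$pos[idx]
    o <- order(p)
    idx <- idx[o]; p <- p[o]
    lo <- findInterval(starts - 1L, p) + 1L  # first pos >= start
    hi <- findInterval(ends, p)              # last pos <= end
    n <- pmax(hi - lo + 1L, 0L)
    keep <- which(n >= min_variants)
    if (!length(keep)) next
    res[[ci]] <- data.table::data.table(
      chrom = ch, start = starts[keep], end = ends[keep],
      n_variants = n[keep],
      variant_idx = lapply(keep, function(k) idx[lo[k]:hi[k]]))
  }
  out <- data.table::rbindlist(res[!vapply(res, is.null, logical(1))])
  if (!nrow(out))
    out <- data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), n_variants = integer(),
                                  variant_idx = list())
  out
}

#' Bin region variants into overlapping sub-windows
#'
#' Sub-windows of `width` bp at `step` bp tiled across the region; a
#' variant interior to the tiling falls in exactly two sub-windows.
#'
#' @param pos Variant positions (1-based, within the region).
#' @param tumor Tumor id per variant.
#' @param start,end Region bounds (1-based inclusive).
#' @param width,step Sub-window geometry (defaults 30/15).
#' @return A `window_grid` list: sub-window `starts`/`ends`, per-variant
#'   sub-window memberships (`win_idx`, `var_idx`), and the per
#'   (sub-window, tumor) counts `l_it` as a data.frame.
#' @export
bin_variants <- function(pos, tumor, start, end, width = 30L, step = 15L) {
  stopifnot(length(pos) == length(tumor))
  if (length(pos) && (any(pos < start) || any(pos > end)))
    stop("variant positions outside the region")
  starts <- seq.int(start, end, step)
  ends <- pmin(starts + width - 1L, end)
  nsub <- length(starts)
  d <- pos - start                       # 0-based offset
  i2 <- d %/% step + 1L                  # sub-window starting at/below pos
  i1 <- i2 - 1L                          # preceding overlapping sub-window
  win_idx <- c(i1, i2)
  var_idx <- c(seq_along(pos), seq_along(pos))
  ok <- win_idx >= 1L & win_idx <= nsub &
    pos[var_idx] <= starts[pmax(win_idx, 1L)] + width - 1L
  win_idx <- win_idx[ok]; var_idx <- var_idx[ok]
  tum_f <- factor(tumor)
  ntum <- nlevels(tum_f)
  l_it <- if (length(win_idx)) {
    key <- (win_idx - 1L) * ntum + as.integer(tum_f)[var_idx]
    if (nsub * ntum <= 500000L) {
      cnt <- tabulate(key, nbins = nsub * ntum)
      k <- which(cnt > 0L)
      cnt <- cnt[k]
    } else {
      agg <- rowsum(rep(1L, length(key)), key)
      k <- as.integer(rownames(agg))
      cnt <- as.integer(agg[, 1])
    }
    fast_df(list(sub_window = (k - 1L) %/% ntum + 1L,
                 tumor_id = levels(tum_f)[(k - 1L) %% ntum + 1L],
                 count = cnt))
  } else fast_df(list(sub_window = integer(), tumor_id = character(),
                      count = integer()))
  structure(list(starts = starts, ends = ends, n_sub = nsub,
                 win_idx = win_idx, var_idx = var_idx, l_it = l_it),
            class = "window_grid")
}

#' Weighted mutational load per sub-window
#'
#' `L_i = sum_t w_t * l_it` over the tumors of the grid.
#'
#' @param grid A `window_grid` from [bin_variants()].
#' @param weights Named numeric vector of per-tumor weights
#'   (see [tumor_weight()]).
#' @return Numeric vector `L` of length `grid$n_sub`.
#' @export
weighted_load <- function(grid, weights) {
  L <- numeric(grid$n_sub)
  l <- grid$l_it
  if (nrow(l)) {
    w <- weights[l$tumor_id]
    if (anyNA(w)) stop("missing tumor weight for: ",
                       paste(unique(l$tumor_id[is.na(w)]), collapse = ", "))
    agg <- rowsum(w * l$count, l$sub_window)
    L[as.integer(rownames(agg))] <- agg[, 1]
  }
  L
}

#' Select hotspot sub-windows from a load vector
#'
#' Sub-window i is a hotspot when `L_i >= max(L)/2`, `L_i > 3*mean(L)`
#' and `L_i >= mean(L) + 3*sd(L)` all hold (sample sd, n-1 denominator;
#' a single-element vector is treated as sd = 0).  The rule is invariant
#' under positive rescaling of `L`.
#'
#' @param L Numeric load vector.
#' @return Integer indices of selected sub-windows (possibly empty).
#' @export
select_hotspot_windows <- function(L) {
  if (!length(L)) stop("empty load vector")
  m <- mean(L)
  s <- if (length(L) > 1L) stats::sd(L) else 0
  which(L >= max(L) / 2 & L > 3 * m & L >= m + 3 * s)
}

#' Prune a candidate window to a hotspot region
#'
#' Composition of [bin_variants()], [weighted_load()] and
#' [select_hotspot_windows()]: returns the member sites falling inside
#' selected sub-windows, with per-site recurrence R (number of distinct
#' carrier tumors of the same `(chrom, pos, alt)`) and carrier lists, or
#' `NULL` when no sub-window is selected.
#'
#' @param chrom,start,end Region coordinates.
#' @param variants Variant table restricted to the region (columns
#'   `tumor_id`, `chrom`, `pos`, `ref`, `alt`).
#' @param weights Named per-tumor weight vector covering all tumors in
#'   `variants`.
#' @param width,step Sub-window geometry (defaults 30/15).
#' @param recurrence_by `"position_allele"` (default; R counts tumors
#'   sharing position and alternate allele) or `"position"`.
#' @return A `hotspot_region` object or `NULL`.
#' @export
prune_region <- function(chrom, start, end, variants, weights,
                         width = 30L, step = 15L,
                         recurrence_by = c("position_allele", "position")) {
  recurrence_by <- match.arg(recurrence_by)
  if (!length(variants$pos)) return(NULL)
  grid <- bin_variants(variants$pos, variants$tumor_id, start, end,
                       width = width, step = step)
  L <- weighted_load(grid, weights)
  sel <- select_hotspot_windows(L)
  if (!length(sel)) return(NULL)
  in_sel <- unique(grid$var_idx[grid$win_idx %in% sel])
  mem <- data.table::data.table(
    tumor_id = variants$tumor_id[in_sel], chrom = variants$chrom[in_sel],
    pos = variants$pos[in_sel], ref = variants$ref[in_sel],
    alt = variants$alt[in_sel])
  site_tab <- if (recurrence_by == "position_allele")
    mem[, list(ref = ref[1], R = length(unique(tumor_id)),
               carriers = list(unique(tumor_id))),
        by = c("chrom", "pos", "alt")]
  else
    mem[, list(ref = ref[1], alt = alt[1], R = length(unique(tumor_id)),
               carriers = list(unique(tumor_id))),
        by = c("chrom", "pos")]
  data.table::setcolorder(site_tab, c("chrom", "pos", "ref", "alt"))
  data.table::setorderv(site_tab, c("chrom", "pos", "alt"))
  structure(list(chrom = chrom, start = start, end = end,
                 sites = site_tab, selected_sub_windows = sel,
                 sub_window_starts = grid$starts[sel], load = L),
            class = "hotspot_region")
}

#' @export
print.hotspot_region <- function(x, ...) {
  cat("hotspot region ", x$chrom, ":", x$start, "-", x$end, "  (",
      nrow(x$sites), " site(s), max R = ", max(x$sites$R), ")\n", sep = "")
  invisible(x)
}

#' Export hotspot regions as BED
#'
#' Converts 1-based inclusive coordinates to BED's 0-based half-open
#' convention.  One line per member site with columns chrom, start, end,
#' name (`pos:ref>alt`), score (recurrence R).
#'
#' @param hotspots List of `hotspot_region` objects.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_hotspots_bed <- function(hotspots, path) {
  rows <- lapply(hotspots, function(h) {
    data.table::data.table(chrom = h$sites$chrom, start = h$sites$pos - 1L,
                           end = h$sites$pos,
                           name = paste0(h$sites$pos, ":", h$sites$ref, ">",
                                         h$sites$alt),
                           score = h$sites$R)
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
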