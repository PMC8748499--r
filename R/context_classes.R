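## Substitution context classes.
##
## All catalogs use the conventional COSMIC lexicographic ordering:
## substitution types C>A, C>G, C>T, T>A, T>C, T>G (pyrimidine reference
## strand), then 5' flank A,C,G,T, then 3' flank A,C,G,T.  In NxSxN mode the
## "flanks" are the bases two positions up- and downstream of the mutated
## base; the immediate neighbours are collapsed.

.BASES <- c("A", "C", "G", "T")
.SUBS  <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMP  <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Enumerate the 96 substitution context classes
#'
#' Returns the class labels in the conventional COSMIC ordering
#' (`"A[C>A]A"`, `"A[C>A]C"`, ..., `"T[T>G]T"`).  The same 96 labels are
#' used for trinucleotide catalogs (flanks at -1/+1) and NxSxN
#' penta-reduced catalogs (flanks at -2/+2); the `context_mode` of a
#' catalog records which convention produced it.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(context_classes_96())
context_classes_96 <- function() {
  grid <- expand.grid(f3 = .BASES, f5 = .BASES, sub = .SUBS,
                      stringsAsFactors = FALSE)
  ref <- substr(grid$sub, 1, 1)
  alt <- substr(grid$sub, 3, 3)
  paste0(grid$f5, "[", ref, ">", alt, "]", grid$f3)
}

#' Enumerate the 1536 penta-nucleotide context classes
#'
#' Full penta-nucleotide classes indexed by substitution type and the four
#' flanking bases at positions -2, -1, +1, +2 (6 x 4 x 4 x 4 x 4 = 1536).
#' Labels have the form `"AC[C>T]GA"` with the -2 base first.
#'
#' @return Character vector of length 1536.
#' @export
penta_classes_1536 <- function() {
  grid <- expand.grid(p2 = .BASES, p1 = .BASES, m1 = .BASES, m2 = .BASES,
                      sub = .SUBS, stringsAsFactors = FALSE)
  ref <- substr(grid$sub, 1, 1)
  alt <- substr(grid$sub, 3, 3)
  paste0(grid$m2, grid$m1, "[", ref, ">", alt, "]", grid$p1, grid$p2)
}

#' Collapse 1536 penta-nucleotide counts to 96 NxSxN classes
#'
#' Each NxSxN class (substitution type plus -2/+2 flanks) is the sum over
#' the 16 combinations of the omitted -1/+1 bases.  The map is a linear
#' surjection with disjoint 16-element preimages, so totals are conserved.
#'
#' @param p Numeric vector of length 1536 ordered as [penta_classes_1536()].
#' @return Numeric vector of length 96 ordered as [context_classes_96()].
#' @export
reduce_penta_to_nxsxn <- function(p) {
  if (length(p) != 1536L)
    stop("penta count vector must have length 1536, got ", length(p))
  idx <- penta_to_nxsxn_map()
  as.vector(rowsum(as.numeric(p), idx)[as.character(1:96), 1])
}

#' Index map from 1536 penta classes to 96 NxSxN classes
#'
#' @return Integer vector of length 1536; element i is the NxSxN class
#'   index (1-96) of penta class i.
#' @export
penta_to_nxsxn_map <- function() {
  grid <- expand.grid(p2 = .BASES, p1 = .BASES, m1 = .BASES, m2 = .BASES,
                      sub = .SUBS, stringsAsFactors = FALSE)
  sub_i <- match(grid$sub, .SUBS) - 1L
  m2_i  <- match(grid$m2, .BASES) - 1L
  p2_i  <- match(grid$p2, .BASES) - 1L
  sub_i * 16L + m2_i * 4L + p2_i + 1L
}

## Reverse complement for plain character vectors of single bases.
.revcomp_base <- function(x) unname(.COMP[x])

#' Classify substitutions into 96 context classes
#'
#' Assigns each single-base substitution to one of the 96 context classes,
#' reading flanking bases from a reference sequence.  Purine-reference
#' substitutions are reverse-complemented to the pyrimidine strand before
#' classification.  In `"trinucleotide"` mode the -1/+1 neighbours are
#' used; in `"nxsxn"` mode the -2/+2 neighbours are used and the immediate
#' neighbours are ignored.
#'
#' @param genome A named list or character vector of chromosome sequences,
#'   or a [Biostrings::DNAStringSet].
#' @param chrom,pos,ref,alt Vectors describing the substitutions
#'   (`pos` 1-based; `ref`, `alt` single bases).
#' @param mode `"trinucleotide"` (default) or `"nxsxn"`.
#' @return Integer vector of class indices (1-96, ordering of
#'   [context_classes_96()]); `NA` for substitutions whose required flanks
#'   contain `N` or fall off the chromosome ends (a message reports the
#'   excluded count).  A genome/`ref` mismatch is an error.
#' @export
classify_context <- function(genome, chrom, pos, ref, alt,
                             mode = c("trinucleotide", "nxsxn")) {
  mode <- match.arg(mode)
  genome <- as_genome_strings(genome)
  n <- length(pos)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n)
  off <- if (mode == "trinucleotide") 1L else 2L

  up <- dn <- gref <- character(n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome))
      stop("chromosome '", ch, "' not present in the reference")
    sel <- which(chrom == ch)
    seqch <- genome[[ch]]
    len <- nchar(seqch)
    p <- pos[sel]
    if (any(p < 1L | p > len))
      stop("position outside chromosome '", ch, "'")
    gref[sel] <- substr_vec(seqch, p, p)
    up[sel] <- ifelse(p - off >= 1L, substr_vec(seqch, p - off, p - off), "N")
    dn[sel] <- ifelse(p + off <= len, substr_vec(seqch, p + off, p + off), "N")
  }
  bad <- gref != toupper(ref)
  if (any(bad))
    stop("reference mismatch at ", sum(bad), " site(s), first at ",
         chrom[which(bad)[1]], ":", pos[which(bad)[1]],
         " (genome ", gref[which(bad)[1]], ", ref ", ref[which(bad)[1]], ")")

  ## integer codes A=1 C=2 G=3 T=4; complement is 5 - code
  rc <- match(toupper(ref), .BASES)
  ac <- match(toupper(alt), .BASES)
  up_c <- match(up, .BASES)
  dn_c <- match(dn, .BASES)
  flip <- rc == 1L | rc == 3L                      # purine reference
  r2 <- rc; r2[flip] <- 5L - rc[flip]              # 2 (C) or 4 (T)
  a2 <- ac; a2[flip] <- 5L - ac[flip]
  f5_i <- up_c; f5_i[flip] <- 5L - dn_c[flip]
  f3_i <- dn_c; f3_i[flip] <- 5L - up_c[flip]

  ## substitution index within the pyrimidine set:
  ## C>{A,G,T} -> 1..3, T>{A,C,G} -> 4..6
  sub_i <- ifelse(r2 == 2L, match(a2, c(1L, 3L, 4L)),
                  3L + match(a2, c(1L, 2L, 3L)))
  idx <- (sub_i - 1L) * 16L + (f5_i - 1L) * 4L + (f3_i - 1L) + 1L
  n_excl <- sum(is.na(idx))
  if (n_excl > 0L)
    message(n_excl, " variant(s) unclassifiable (N or truncated flank) and excluded")
  idx
}

## Coerce supported genome representations to a named list of upper-case
## character strings.
as_genome_strings <- function(genome) {
  if (inherits(genome, "DNAStringSet"))
    genome <- as.character(genome)
  if (is.character(genome)) genome <- as.list(genome)
  if (!is.list(genome) || is.null(names(genome)))
    stop("genome must be a named character vector/list or a DNAStringSet")
  lapply(genome, function(s) toupper(as.character(s)))
}

## Vectorised substr over positions of a single string.
substr_vec <- function(s, start, stop) {
  substring(s, start, stop)
}

#' Build a tumors x 96 mutation catalog
#'
#' Classifies every variant with [classify_context()] and tabulates counts
#' per tumor.  Row sums equal each tumor's count of classifiable variants;
#' unclassifiable variants (N/truncated flanks) are excluded with a message.
#'
#' @param variants A variant table (see [read_variant_table()]).
#' @param genome Reference sequences (see [classify_context()]).
#' @param mode `"trinucleotide"` or `"nxsxn"`.
#' @param tumors Optional character vector fixing the row set/order;
#'   defaults to the tumors present in `variants`.
#' @return Integer matrix tumors x 96 with `context_mode` attribute and
#'   class labels as column names.
#' @export
build_catalog <- function(variants, genome, mode = c("trinucleotide", "nxsxn"),
                          tumors = NULL) {
  mode <- match.arg(mode)
  if (is.null(tumors)) tumors <- sort(unique(variants$tumor_id))
  cls <- if (nrow(variants))
    classify_context(genome, variants$chrom, variants$pos,
                     variants$ref, variants$alt, mode = mode)
  else integer(0)
  keep <- !is.na(cls)
  tum <- factor(variants$tumor_id[keep], levels = tumors)
  if (anyNA(tum)) stop("variant table contains tumors absent from 'tumors'")
  cat <- table(tum, factor(cls[keep], levels = 1:96))
  m <- matrix(as.integer(cat), nrow = length(tumors), ncol = 96L,
              dimnames = list(tumors, context_classes_96()))
  attr(m, "context_mode") <- mode
  attr(m, "n_unclassifiable") <- sum(!keep)
  m
}
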