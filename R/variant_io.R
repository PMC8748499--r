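## Somatic variant table I/O and filtering.
##
## The in-memory variant table is a data.table with columns
## tumor_id, chrom, pos (1-based), ref, alt -- one row per somatic
## single-nucleotide substitution.  Coordinates are 1-based inclusive
## throughout the package (MAF/VCF convention); BED interaction converts
## at the boundary.

## Column synonyms accepted for the MAF-like dialect (case-insensitive).
.MAF_SYNONYMS <- list(
  tumor_id = c("tumor_id", "tumor_sample_barcode", "sample", "sample_id"),
  chrom    = c("chrom", "chromosome", "chr"),
  pos      = c("pos", "position", "start_position", "start"),
  ref      = c("ref", "reference_allele", "ref_allele"),
  alt      = c("alt", "tumor_seq_allele2", "alt_allele", "alternate_allele")
)

#' Read a somatic variant table
#'
#' Reads somatic SNVs from a MAF-like TSV (minimal columns `tumor_id`,
#' `chrom`, `pos`, `ref`, `alt`, with the usual MAF header synonyms
#' accepted and extra columns ignored) or a VCF.  Only A/C/G/T to A/C/G/T
#' single-base substitutions are retained; indels and MNVs are dropped
#' with a message reporting the count, and multi-allelic VCF ALT fields
#' are split into one record per alternate allele.
#'
#' @param path Path to the input file.
#' @param format `"maf"` (MAF-like TSV, default) or `"vcf"`.
#' @param tumor_id For single-sample VCFs without genotype columns, the
#'   tumor identifier to assign (defaults to the VCF sample name or the
#'   file stem).
#' @return A `data.table` with columns `tumor_id`, `chrom`, `pos`, `ref`,
#'   `alt`; attribute `n_dropped` counts excluded non-SNV records.
#' @export
read_variant_table <- function(path, format = c("maf", "vcf"), tumor_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  v <- switch(format,
    maf = read_variant_maf(path),
    vcf = read_variant_vcf(path, tumor_id = tumor_id))
  validate_variant_table(v)
  v
}

read_variant_maf <- function(path) {
  raw <- tryCatch(
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = list(character = 1:2)),
    error = function(e) stop("cannot parse '", path, "' as TSV: ",
                             conditionMessage(e)))
  lc <- tolower(names(raw))
  cols <- vapply(names(.MAF_SYNONYMS), function(k) {
    hit <- which(lc %in% .MAF_SYNONYMS[[k]])
    if (!length(hit)) {
      if (k == "tumor_id")
        stop("schema error: no tumor identifier column in '", path,
             "' (expected one of: ",
             paste(.MAF_SYNONYMS$tumor_id, collapse = ", "), ")")
      stop("schema error: missing required column '", k, "' in '", path, "'")
    }
    hit[1]
  }, integer(1))
  v <- raw[, cols, with = FALSE]
  data.table::setnames(v, names(.MAF_SYNONYMS))
  v[, `:=`(tumor_id = as.character(tumor_id), chrom = as.character(chrom),
           pos = as.integer(pos), ref = toupper(as.character(ref)),
           alt = toupper(as.character(alt)))]
  keep_snv(v)
}

read_variant_vcf <- function(path, tumor_id = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("cannot parse '", path,
                                           "' as VCF: ", conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (is.null(tumor_id)) {
    smp <- colnames(vcf@gt)
    smp <- setdiff(smp, "FORMAT")
    tumor_id <- if (length(smp) >= 1) smp[1] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  alt_split <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  nalt <- lengths(alt_split)
  v <- data.table::data.table(
    tumor_id = tumor_id,
    chrom = rep(fix$CHROM, nalt),
    pos = rep(as.integer(fix$POS), nalt),
    ref = toupper(rep(fix$REF, nalt)),
    alt = toupper(unlist(alt_split)))
  keep_snv(v)
}

## Retain only single-base A/C/G/T substitutions with ref != alt.
keep_snv <- function(v) {
  ok <- v$ref %in% .BASES & v$alt %in% .BASES & v$ref != v$alt
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " non-SNV record(s) dropped (indels/MNVs/identical alleles)")
  out <- v[ok]
  data.table::setattr(out, "n_dropped", n_dropped)
  out
}

#' Validate a variant table
#'
#' Checks the variant-table contract: required columns, single-base
#' A/C/G/T alleles with `ref != alt`, and uniqueness of
#' `(tumor_id, chrom, pos, alt)`.
#'
#' @param v A variant table.
#' @return `v` invisibly; errors on violation.
#' @export
validate_variant_table <- function(v) {
  need <- c("tumor_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v)))
    stop("variant table missing column(s): ",
         paste(setdiff(need, names(v)), collapse = ", "))
  if (nrow(v)) {
    if (!all(v$ref %in% .BASES) || !all(v$alt %in% .BASES))
      stop("variant table contains non-ACGT alleles")
    if (any(v$ref == v$alt)) stop("variant table contains ref == alt records")
    if (anyDuplicated(v[, c("tumor_id", "chrom", "pos", "alt")]))
      stop("duplicate (tumor_id, chrom, pos, alt) records")
  }
  invisible(v)
}

#' Write a variant table as TSV
#'
#' @param v A variant table.
#' @param path Output path.
#' @return `path` invisibly.
#' @export
write_variant_table <- function(v, path) {
  data.table::fwrite(v[, c("tumor_id", "chrom", "pos", "ref", "alt")],
                     path, sep = "\t")
  invisible(path)
}

#' Read a panel-of-normals blacklist
#'
#' TSV with columns `chrom`, `pos`, `alt`, `fraction` where `fraction` is
#' the fraction of panel samples carrying the variant (in \[0, 1\]).
#'
#' @param path Path to the TSV.
#' @return A keyed `data.table`.
#' @export
read_panel_of_normals <- function(path) {
  p <- data.table::fread(path, sep = "\t", header = TRUE,
                         colClasses = list(character = "chrom"))
  need <- c("chrom", "pos", "alt", "fraction")
  if (!all(need %in% names(p)))
    stop("panel of normals missing column(s): ",
         paste(setdiff(need, names(p)), collapse = ", "))
  if (any(p$fraction < 0 | p$fraction > 1))
    stop("panel fractions must lie in [0, 1]")
  data.table::setkeyv(p, c("chrom", "pos", "alt"))
  p
}

#' Remove recurrent technical artifacts using a panel of normals
#'
#' Removes every record whose `(chrom, pos, alt)` is carried by more than
#' `max_fraction` of the panel samples (strict inequality, the literal
#' reading of "over 1\%").  Variants absent from the panel are treated as
#' fraction 0 and retained.
#'
#' @param v A variant table.
#' @param panel A panel table from [read_panel_of_normals()] (or any
#'   data.frame with `chrom`, `pos`, `alt`, `fraction`).
#' @param max_fraction Removal threshold, default 0.01.
#' @return The filtered variant table; attribute `n_panel_removed` counts
#'   removed records.
#' @export
filter_panel_artifacts <- function(v, panel, max_fraction = 0.01) {
  stopifnot(max_fraction > 0, max_fraction <= 1)
  panel <- data.table::as.data.table(panel)
  bad <- panel[fraction > max_fraction, c("chrom", "pos", "alt")]
  if (!nrow(bad) || !nrow(v)) {
    out <- data.table::copy(data.table::as.data.table(v))
    data.table::setattr(out, "n_panel_removed", 0L)
    return(out)
  }
  key <- paste(v$chrom, v$pos, v$alt)
  drop <- key %in% paste(bad$chrom, bad$pos, bad$alt)
  out <- data.table::as.data.table(v)[!drop]
  data.table::setattr(out, "n_panel_removed", sum(drop))
  out
}

#' Compute per-tumor mutational loads
#'
#' The per-tumor total somatic SNV count (the mutational load used for
#' the pruning weights and the `nvar` covariate of the association model).
#' Tumors listed in `metadata` but absent from the table get load 0.
#'
#' @param v A (filtered) variant table.
#' @param metadata A data.frame with columns `tumor_id`, `entity`, `sex`
#'   (sex levels `female`/`male`/`unknown`); or a character vector of
#'   tumor ids, in which case entity/sex default to a single level and
#'   `unknown`.
#' @return A `data.table` with columns `tumor_id`, `entity`, `sex`,
#'   `total_load`.
#' @export
compute_tumor_loads <- function(v, metadata) {
  if (is.character(metadata))
    metadata <- data.frame(tumor_id = metadata, entity = "cohort",
                           sex = "unknown", stringsAsFactors = FALSE)
  md <- data.table::as.data.table(metadata)
  need <- c("tumor_id", "entity", "sex")
  if (!all(need %in% names(md)))
    stop("metadata missing column(s): ",
         paste(setdiff(need, names(md)), collapse = ", "))
  unknown <- setdiff(unique(v$tumor_id), md$tumor_id)
  if (length(unknown))
    stop("variant table contains tumor(s) absent from metadata: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  out <- md[, c("tumor_id", "entity", "sex")]
  if (nrow(v)) {
    cnt <- data.table::as.data.table(v)[, list(n = .N), by = "tumor_id"]
    out$total_load <- cnt$n[match(out$tumor_id, cnt$tumor_id)]
    out$total_load[is.na(out$total_load)] <- 0L
  } else out$total_load <- 0L
  out
}
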