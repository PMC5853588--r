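# Per-site editing-extent quantification: from counts directly, or from
# strand-specific alignments by pileup at annotated C targets.

#' Editing extent of a site
#'
#' The fraction of informative reads showing the edited base:
#' edited / (edited + unedited). Reads showing any other base are excluded
#' from the denominator. Undefined (NA) when no informative reads exist.
#'
#' @param edited,unedited non-negative integer vectors.
#' @return Numeric vector of extents in [0, 1]; \code{NA} where
#'   \code{edited + unedited == 0}.
#' @examples
#' editing_extent(900, 100) # 0.9
#' editing_extent(0, 0)     # NA
#' @export
editing_extent <- function(edited, unedited) {
  if (any(edited < 0, na.rm = TRUE) || any(unedited < 0, na.rm = TRUE)) {
    abort("counts must be non-negative")
  }
  denom <- edited + unedited
  out <- edited / denom
  out[denom == 0] <- NA_real_
  out
}

#' Count edited/unedited/other bases by pileup at annotated sites
#'
#' For each annotated C target, counts aligned reads by the base they show
#' at the target position, read on the transcript sense strand: T is
#' edited, C unedited, anything else \code{other}. A read contributes only
#' if (i) it aligns to the annotated strand of the transcript (the library
#' is strand-specific in sense orientation; antisense alignments are
#' excluded), (ii) its aligned footprint extends at least
#' \code{min_base_anchor} reference bases on each side of the target, and
#' (iii) it aligns a base at the target (reads with a deletion or
#' reference skip over the site carry no base evidence and are dropped).
#'
#' @param sam named character vector of SAM file paths (names are sample
#'   ids; unnamed input uses the file base names).
#' @param sites site annotation with 1-based \code{tx_position} on the
#'   \code{transcript} reference (as produced by \code{\link{gen_sites}};
#'   BED input can be converted with \code{\link{read_sites_bed}}).
#' @param min_base_anchor minimum aligned bases required on each side of
#'   the target (default 3, guarding against terminal misalignment).
#' @return Long \code{data.frame}: \code{site_id}, \code{sample_id},
#'   \code{edited}, \code{unedited}, \code{other}.
#' @export
pileup_counts <- function(sam, sites, min_base_anchor = 3L) {
  if (is.null(names(sam))) {
    names(sam) <- sub("\\.sam$", "", basename(sam))
  }
  out <- lapply(names(sam), function(s) {
    counts <- .pileup_one(sam[[s]], sites, min_base_anchor)
    counts$sample_id <- s
    counts
  })
  out <- do.call(rbind, out)
  out[c("site_id", "sample_id", "edited", "unedited", "other")]
}

.read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(what = c("seq", "flag")))
}

.pileup_one <- function(path, sites, min_base_anchor) {
  ga <- .read_sam(path)
  n <- nrow(sites)
  edited <- unedited <- other <- integer(n)
  if (length(ga) > 0 && n > 0) {
    known <- sites$transcript %in% GenomeInfoDb::seqlevels(ga)
    if (!all(known)) {
      abort("sites on sequences absent from the alignment reference: ",
            paste(unique(sites$transcript[!known]), collapse = ", "))
    }
    # anchor windows must lie within the aligned footprint of a read
    windows <- GenomicRanges::GRanges(
      sites$transcript,
      IRanges::IRanges(sites$tx_position - min_base_anchor,
                       sites$tx_position + min_base_anchor),
      strand = sites$strand
    )
    GenomeInfoDb::seqlevels(windows) <- GenomeInfoDb::seqlevels(ga)
    hits <- GenomicRanges::findOverlaps(windows, GenomicRanges::granges(ga),
                                        type = "within",
                                        ignore.strand = FALSE)
    if (length(hits) > 0) {
      si <- S4Vectors::queryHits(hits)
      ri <- S4Vectors::subjectHits(hits)
      qpos <- .query_position(ga[ri], sites$tx_position[si])
      keep <- !is.na(qpos) # deletion/skip over the target: no evidence
      si <- si[keep]; ri <- ri[keep]; qpos <- qpos[keep]
      bases <- substring(as.character(S4Vectors::mcols(ga)$seq[ri]),
                         qpos, qpos)
      sense <- ifelse(sites$strand[si] == "-", complement_base(bases),
                      bases)
      tab <- function(b) tabulate(si[sense == b], nbins = n)
      edited <- tab("T")
      unedited <- tab("C")
      other <- tabulate(si[!(sense %in% c("T", "C"))], nbins = n)
    }
  }
  data.frame(site_id = sites$site_id, edited = edited,
             unedited = unedited, other = other,
             stringsAsFactors = FALSE)
}

# 1-based position in the query (stored SEQ) of reference position refpos,
# or NA if the alignment has no aligned base there. Vectorised over
# (alignment, refpos) pairs.
.query_position <- function(ga, refpos) {
  rranges <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    GenomicAlignments::cigar(ga), pos = BiocGenerics::start(ga),
    ops = "M")
  qranges <- GenomicAlignments::cigarRangesAlongQuerySpace(
    GenomicAlignments::cigar(ga), ops = "M")
  out <- rep(NA_integer_, length(ga))
  nblocks <- S4Vectors::elementNROWS(rranges)
  idx <- rep(seq_along(ga), nblocks)
  rs <- unlist(IRanges::start(rranges), use.names = FALSE)
  re <- unlist(IRanges::end(rranges), use.names = FALSE)
  qs <- unlist(IRanges::start(qranges), use.names = FALSE)
  p <- refpos[idx]
  hit <- which(p >= rs & p <= re)
  out[idx[hit]] <- qs[hit] + (p[hit] - rs[hit])
  out
}

#' Read a BED site annotation
#'
#' Converts a 0-based half-open BED file of single-base C targets into the
#' package's native 1-based annotation.
#'
#' @param path BED file (chrom, start, end, name, score, strand).
#' @return Site annotation \code{data.frame}.
#' @export
read_sites_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) abort("BED annotation needs 6 columns")
  names(bed)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (any(bed$end - bed$start != 1L)) {
    abort("editing-site BED intervals must be single bases")
  }
  data.frame(
    site_id = bed$name,
    transcript = bed$chrom,
    organelle = NA_character_,
    complex_group = NA_character_,
    strand = bed$strand,
    tx_position = bed$start + 1L, # back to 1-based
    genome_position = NA_integer_,
    stringsAsFactors = FALSE
  )
}
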