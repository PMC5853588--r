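# Intron splicing efficiency from junction-informative alignments, and
# the same ratio applied to amplicon expression levels.

#' Splicing efficiency
#'
#' spliced / (spliced + unspliced). Inputs may be junction read counts or
#' relative amplicon expression levels (the ratio is the same in both
#' assays); undefined when both are zero.
#'
#' @param spliced,unspliced non-negative counts or expression levels
#'   (vectorised).
#' @return Fraction in [0, 1], \code{NA} at zero denominator.
#' @examples
#' splicing_efficiency(95, 5) # 0.95
#' @export
splicing_efficiency <- function(spliced, unspliced) {
  if (any(spliced < 0, na.rm = TRUE) || any(unspliced < 0, na.rm = TRUE)) {
    abort("inputs must be non-negative")
  }
  denom <- spliced + unspliced
  out <- spliced / denom
  out[denom == 0] <- NA_real_
  out
}

#' Count junction-informative alignments over an intron
#'
#' \code{spliced}: alignments containing exactly one reference skip whose
#' span matches the annotated intron (within \code{tolerance} nt at each
#' end; default exact) and with at least \code{anchor} aligned bases on
#' each flanking exon. \code{unspliced}: ungapped alignments covering an
#' exon-intron boundary with at least \code{anchor} bases on both the
#' exon and the intron side; both boundaries are counted and summed.
#' Alignments lying entirely within the intron or an exon touch no
#' boundary and contribute to neither category.
#'
#' @param sam path to a SAM file (or a \code{GAlignments} object).
#' @param intron an \code{\link{intron_model}}.
#' @param anchor minimum aligned bases on each side of a junction or
#'   boundary (default 6).
#' @param tolerance allowed deviation of the gap from the annotated
#'   intron, in nt per end (default 0: exact match).
#' @return Named integer vector \code{c(spliced = , unspliced = )}.
#' @export
junction_counts <- function(sam, intron, anchor = 6L, tolerance = 0L) {
  stopifnot(inherits(intron, "intron_model"))
  if (anchor < 1) abort("anchor must be >= 1")
  ga <- if (is.character(sam)) .read_sam(sam) else sam
  on_tx <- as.character(GenomicAlignments::seqnames(ga)) ==
    intron$transcript
  ga <- ga[on_tx]
  if (length(ga) == 0) return(c(spliced = 0L, unspliced = 0L))

  is_ <- intron$intron_start
  ie <- intron$intron_end
  cig <- GenomicAlignments::cigar(ga)
  starts <- BiocGenerics::start(ga)
  ends <- BiocGenerics::end(ga)
  njunc <- GenomicAlignments::njunc(ga)

  spliced <- 0L
  gapped <- which(njunc == 1L)
  if (length(gapped)) {
    gaps <- GenomicAlignments::cigarRangesAlongReferenceSpace(
      cig[gapped], pos = starts[gapped], ops = "N")
    gs <- unlist(IRanges::start(gaps), use.names = FALSE)
    ge <- unlist(IRanges::end(gaps), use.names = FALSE)
    match_gap <- abs(gs - is_) <= tolerance & abs(ge - ie) <= tolerance
    left_anchor <- gs - starts[gapped] >= anchor
    right_anchor <- ends[gapped] - ge >= anchor
    spliced <- sum(match_gap & left_anchor & right_anchor)
  }

  ungapped <- njunc == 0L
  # left boundary: last exon1 base is is_-1, first intron base is is_
  left <- ungapped & starts <= is_ - anchor & ends >= is_ + anchor - 1L
  # right boundary: last intron base is ie, first exon2 base is ie+1
  right <- ungapped & starts <= ie - anchor + 1L & ends >= ie + anchor
  c(spliced = as.integer(spliced),
    unspliced = as.integer(sum(left) + sum(right)))
}

#' Per-genotype splicing-efficiency report
#'
#' Tabulates mean efficiency and dispersion per genotype and, when two or
#' more genotypes are present, the unequal-variance (Welch) two-sample t
#' statistic between each genotype and the reference. The t statistic is
#' a display statistic over few biological replicates and is flagged as
#' descriptive only.
#'
#' @param records \code{data.frame} with columns \code{sample_id},
#'   \code{genotype}, \code{spliced}, \code{unspliced} (or a precomputed
#'   \code{efficiency} column). Records with undefined efficiency are
#'   excluded with a message.
#' @param reference reference genotype for the pairwise comparison
#'   (default: first genotype).
#' @return A list with \code{table} (per-genotype n, mean, sd) and
#'   \code{comparisons} (genotype vs reference, t and p, descriptive
#'   only; \code{NULL} with a single genotype).
#' @export
splicing_report <- function(records, reference = NULL) {
  if (is.null(records$efficiency)) {
    records$efficiency <- splicing_efficiency(records$spliced,
                                              records$unspliced)
  }
  drop <- is.na(records$efficiency)
  if (any(drop)) {
    message(sum(drop), " record(s) with undefined efficiency excluded")
    records <- records[!drop, ]
  }
  if (nrow(records) == 0) abort("no records with defined efficiency")
  genotypes <- unique(records$genotype)
  tab <- do.call(rbind, lapply(genotypes, function(g) {
    e <- records$efficiency[records$genotype == g]
    data.frame(genotype = g, n = length(e), mean_efficiency = mean(e),
               sd_efficiency = if (length(e) > 1) sd(e) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  reference <- reference %||% genotypes[1]
  comparisons <- NULL
  others <- setdiff(genotypes, reference)
  if (length(others)) {
    comparisons <- do.call(rbind, lapply(others, function(g) {
      x <- records$efficiency[records$genotype == reference]
      y <- records$efficiency[records$genotype == g]
      if (length(x) < 2 || length(y) < 2) {
        return(data.frame(genotype = g, reference = reference,
                          t = NA_real_, p = NA_real_,
                          note = "too few replicates"))
      }
      if (sd(x) == 0 && sd(y) == 0) {
        # degenerate: identical within groups; t is 0 iff means agree
        t_stat <- if (mean(x) == mean(y)) 0 else Inf * sign(mean(y) - mean(x))
        return(data.frame(genotype = g, reference = reference,
                          t = t_stat, p = NA_real_,
                          note = "zero within-group variance"))
      }
      tt <- t.test(y, x, var.equal = FALSE)
      data.frame(genotype = g, reference = reference,
                 t = unname(tt$statistic), p = tt$p.value,
                 note = "descriptive only", stringsAsFactors = FALSE)
    }))
  }
  list(table = tab, comparisons = comparisons)
}
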