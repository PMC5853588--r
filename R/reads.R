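# Synthetic strand-specific alignments: site-covering reads for pileup and
# gapped/ungapped reads over an intron for the splicing analysis.

#' Define a toy intron model
#'
#' Coordinates are 1-based inclusive on the transcript's toy reference:
#' exon1 = [1, intron_start-1], intron = [intron_start, intron_end],
#' exon2 = [intron_end+1, tx_end]. True splicing efficiency is given per
#' genotype.
#'
#' @param intron_id identifier, e.g. \code{"nad5_i1"}.
#' @param transcript transcript (reference sequence) name.
#' @param intron_start,intron_end 1-based inclusive intron bounds.
#' @param tx_end transcript length.
#' @param efficiency named numeric vector of true splicing efficiencies in
#'   [0, 1], one per genotype.
#' @return A list of class \code{intron_model}.
#' @export
intron_model <- function(intron_id, transcript, intron_start, intron_end,
                         tx_end, efficiency) {
  if (intron_end < intron_start) abort("intron must be at least 1 nt")
  if (intron_start < 2 || intron_end >= tx_end) {
    abort("intron must be flanked by exons on both sides")
  }
  if (any(efficiency < 0 | efficiency > 1)) {
    abort("splicing efficiencies must be in [0, 1]")
  }
  structure(
    list(intron_id = intron_id, transcript = transcript,
         intron_start = as.integer(intron_start),
         intron_end = as.integer(intron_end),
         tx_end = as.integer(tx_end),
         efficiency = efficiency),
    class = "intron_model"
  )
}

# Build toy per-transcript reference sequences consistent with the site
# annotation: random bases except that every annotated C target carries C
# on its sense strand (reference-forward C on '+' transcripts, G on '-').
build_toy_reference <- function(sites, intron = NULL, seed = 1) {
  tx <- unique(sites$transcript)
  lens <- setNames(
    vapply(tx, function(t) max(sites$tx_position[sites$transcript == t]) +
             100L, integer(1)),
    tx)
  if (!is.null(intron)) {
    prev <- if (intron$transcript %in% names(lens))
      lens[[intron$transcript]] else 0L
    lens[intron$transcript] <- max(prev, intron$tx_end)
    if (!intron$transcript %in% tx) tx <- c(tx, intron$transcript)
  }
  with_seed(seed, {
    seqs <- lapply(tx, function(t) {
      s <- sample(c("A", "C", "G", "T"), lens[[t]], replace = TRUE)
      here <- sites$transcript == t
      if (any(here)) {
        s[sites$tx_position[here]] <-
          ifelse(sites$strand[here] == "+", "C", "G")
      }
      paste(s, collapse = "")
    })
    setNames(seqs, tx)
  })
}

# Minimal SAM text emission (header + mandatory fields). qual is left as
# '*' throughout: quality scores are out of scope for the generator.
write_sam <- function(records, seq_lengths, path) {
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    paste0("@SQ\tSN:", names(seq_lengths), "\tLN:", seq_lengths)
  )
  lines <- if (nrow(records)) {
    paste(records$qname, records$flag, records$rname, records$pos, 60L,
          records$cigar, "*", 0L, 0L, records$seq, "*", sep = "\t")
  } else {
    character()
  }
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Generate synthetic strand-specific alignments
#'
#' Writes one SAM file per sample under \code{dir}, together with the toy
#' reference (FASTA) and a truth sidecar TSV. Site-covering reads carry T
#' at the target with probability equal to the genotype's true extent and
#' C otherwise (sense-strand convention: on '-' transcripts the emitted
#' reference-forward base is the complement, and the alignment carries the
#' reverse-strand flag). Reads over the intron are gapped (CIGAR N spanning
#' the intron exactly) with probability equal to the genotype's true
#' splicing efficiency, ungapped across an exon-intron boundary otherwise.
#'
#' @param truth a \code{truth_table}.
#' @param design sample design table.
#' @param reads_per_site covering reads generated per site per sample.
#' @param intron optional \code{\link{intron_model}}; if supplied,
#'   \code{intron_reads} junction-informative reads are generated per
#'   sample.
#' @param intron_reads reads over the intron locus per sample.
#' @param read_length read length in nt (must leave at least
#'   \code{2 * min_anchor} aligned bases around any junction).
#' @param min_anchor minimum flanking bases guaranteed on each side of a
#'   site or junction (default 6).
#' @param seed integer seed.
#' @param dir output directory (created if absent).
#' @param error_rate probability a site-covering read carries a base that
#'   is neither sense-C nor sense-T (default 0).
#' @param antisense_fraction fraction of site-covering reads emitted on
#'   the wrong strand (default 0; used to exercise strand exclusion).
#' @return Invisibly, a list with \code{sam} (named per-sample paths),
#'   \code{reference} (FASTA path), \code{sidecar} (truth TSV path) and
#'   \code{seq_lengths}.
#' @export
gen_reads <- function(truth, design, reads_per_site = 200,
                      intron = NULL, intron_reads = 0,
                      read_length = 100L, min_anchor = 6L, seed = 1,
                      dir = tempfile("orgedit_reads_"),
                      error_rate = 0, antisense_fraction = 0) {
  stopifnot(inherits(truth, "truth_table"))
  if (read_length < 2 * min_anchor) {
    abort("read_length must be at least 2 * min_anchor")
  }
  if (!is.null(intron) && intron_reads > 0) {
    if (!all(design$genotype %in% names(intron$efficiency))) {
      abort("intron model lacks efficiencies for some genotypes")
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  refs <- build_toy_reference(truth$sites, intron, seed = seed)
  seq_lengths <- vapply(refs, nchar, integer(1))

  ref_path <- file.path(dir, "reference.fa")
  writeLines(unlist(lapply(names(refs), function(n)
    c(paste0(">", n), refs[[n]]))), ref_path)

  sites <- truth$sites
  sam_paths <- setNames(file.path(dir, paste0(design$sample_id, ".sam")),
                        design$sample_id)

  with_seed(seed, {
    for (j in seq_len(nrow(design))) {
      g <- design$genotype[j]
      recs <- list()
      if (nrow(sites) > 0 && reads_per_site > 0) {
        recs[[length(recs) + 1L]] <-
          .site_reads(sites, truth$extents[, g], refs, reads_per_site,
                      read_length, min_anchor, error_rate,
                      antisense_fraction)
      }
      if (!is.null(intron) && intron_reads > 0) {
        recs[[length(recs) + 1L]] <-
          .intron_reads(intron, intron$efficiency[[g]], refs[[intron$transcript]],
                        intron_reads, read_length, min_anchor)
      }
      recs <- if (length(recs)) do.call(rbind, recs) else
        data.frame(qname = character(), flag = integer(),
                   rname = character(), pos = integer(),
                   cigar = character(), seq = character())
      recs$qname <- sprintf("%s_r%06d", design$sample_id[j],
                            seq_len(nrow(recs)))
      write_sam(recs, seq_lengths, sam_paths[j])
    }
  })

  sidecar <- file.path(dir, "truth_sidecar.tsv")
  sc <- data.frame(
    id = rep(sites$site_id, ncol(truth$extents)),
    genotype = rep(colnames(truth$extents), each = nrow(sites)),
    true_value = as.vector(truth$extents),
    kind = "editing_extent",
    stringsAsFactors = FALSE
  )
  if (!is.null(intron)) {
    sc <- rbind(sc, data.frame(
      id = intron$intron_id,
      genotype = names(intron$efficiency),
      true_value = unname(intron$efficiency),
      kind = "splicing_efficiency",
      stringsAsFactors = FALSE
    ))
  }
  write.table(sc, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(sam = sam_paths, reference = ref_path, sidecar = sidecar,
                 seq_lengths = seq_lengths, dir = dir))
}

.site_reads <- function(sites, extent, refs, n_per_site, read_length,
                        min_anchor, error_rate, antisense_fraction) {
  out <- vector("list", nrow(sites))
  for (i in seq_len(nrow(sites))) {
    tx <- sites$transcript[i]
    pos <- sites$tx_position[i]
    L <- nchar(refs[[tx]])
    lo <- max(1L, pos - read_length + min_anchor)
    hi <- min(L - read_length + 1L, pos - min_anchor + 1L)
    if (hi < lo) abort("read_length too short to anchor site ",
                       sites$site_id[i])
    starts <- sample(lo:hi, n_per_site, replace = TRUE)
    seqs <- substring(refs[[tx]], starts, starts + read_length - 1L)
    # a read drawn for this site carries a sampled editing state at EVERY
    # C target it covers (amplicon reads span neighbouring sites); the
    # focal site is listed first so the error model applies to it
    covered <- which(sites$transcript == tx)
    covered <- covered[order(covered != i)]
    for (j in covered) {
      pj <- sites$tx_position[j]
      on_read <- starts <= pj & pj <= starts + read_length - 1L
      if (!any(on_read)) next
      n_on <- sum(on_read)
      is_edited <- runif(n_on) < extent[[sites$site_id[j]]]
      base <- ifelse(is_edited,
                     if (sites$strand[j] == "+") "T" else "A",
                     if (sites$strand[j] == "+") "C" else "G")
      if (j == i && error_rate > 0) {
        err <- runif(n_on) < error_rate
        # an uninformative base: neither sense-C nor sense-T
        base[err] <- if (sites$strand[j] == "+") "G" else "C"
      }
      at <- pj - starts[on_read] + 1L
      str <- seqs[on_read]
      substr(str, at, at) <- base
      seqs[on_read] <- str
    }
    flag <- if (sites$strand[i] == "+") 0L else 16L
    flags <- rep(flag, n_per_site)
    if (antisense_fraction > 0) {
      anti <- runif(n_per_site) < antisense_fraction
      flags[anti] <- bitwXor(flags[anti], 16L)
    }
    out[[i]] <- data.frame(
      qname = "", flag = flags, rname = tx, pos = starts,
      cigar = paste0(read_length, "M"), seq = seqs,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

.intron_reads <- function(intron, se, ref, n, read_length, min_anchor) {
  n_spliced <- rbinom(1, n, se)
  n_unspliced <- n - n_spliced
  recs <- list()
  is_ <- intron$intron_start
  ie <- intron$intron_end
  ilen <- ie - is_ + 1L
  if (n_spliced > 0) {
    # a = aligned bases on exon1, read ends min_anchor..(L - min_anchor)
    a <- sample(min_anchor:(read_length - min_anchor), n_spliced,
                replace = TRUE)
    b <- read_length - a
    starts <- is_ - a
    seqs <- paste0(substring(ref, starts, is_ - 1L),
                   substring(ref, ie + 1L, ie + b))
    recs[[length(recs) + 1L]] <- data.frame(
      qname = "", flag = 0L, rname = intron$transcript, pos = starts,
      cigar = paste0(a, "M", ilen, "N", b, "M"), seq = seqs,
      stringsAsFactors = FALSE
    )
  }
  if (n_unspliced > 0) {
    # ungapped read across one of the two boundaries, chosen at random,
    # with at least min_anchor bases on each side of it
    left <- runif(n_unspliced) < 0.5
    bpos <- ifelse(left, is_, ie + 1L) # first base on the right of boundary
    lo <- bpos - read_length + min_anchor
    hi <- bpos - min_anchor
    starts <- lo + floor(runif(n_unspliced) * (hi - lo + 1L))
    starts <- pmax(1L, pmin(as.integer(starts),
                            nchar(ref) - read_length + 1L))
    seqs <- substring(ref, starts, starts + read_length - 1L)
    recs[[length(recs) + 1L]] <- data.frame(
      qname = "", flag = 0L, rname = intron$transcript, pos = starts,
      cigar = paste0(read_length, "M"), seq = seqs,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, recs)
}
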