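# Synthetic site annotations: editable C targets on organelle transcripts.

# Transcript name pools used by the generator. Mitochondrial names follow
# the usual organelle gene nomenclature (NADH dehydrogenase, cytochrome c
# biogenesis, ribosomal proteins, ATP synthase, ...); the complex-group
# label is derived from the gene prefix.
.mito_tx_pool <- c(
  "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6", "nad7", "nad9",
  "cob", "cox1", "cox2", "cox3",
  "atp1", "atp4", "atp6", "atp8", "atp9",
  "ccmB", "ccmC", "ccmFc", "ccmFn",
  "rps3", "rps4", "rps12", "rps14", "rpl5", "rpl16",
  "matR", "mttB"
)

.plastid_tx_pool <- c(
  "ndhB", "ndhD", "ndhF", "ndhG", "rpoA", "rpoB", "rpoC1",
  "psbE", "psbF", "petL", "matK", "accD", "clpP", "rps2"
)

.complex_group <- function(transcript) {
  prefix <- sub("[0-9].*$", "", transcript)
  groups <- c(
    nad = "complex I", cob = "complex III", cox = "complex IV",
    atp = "complex V", ccm = "cytochrome c biogenesis",
    rps = "ribosome", rpl = "ribosome",
    mat = "maturase", mtt = "transport",
    ndh = "NDH complex", rpo = "RNA polymerase",
    psb = "photosystem II", pet = "cytochrome b6f",
    acc = "acetyl-CoA carboxylase", clp = "protease"
  )
  out <- unname(groups[substr(prefix, 1, 3)])
  ifelse(is.na(out), "other", out)
}

#' Generate a synthetic editing-site annotation
#'
#' Creates a set of annotated C targets distributed over toy organelle
#' transcripts. Site identifiers follow the \code{"<transcript>_C<position>"}
#' convention used for organelle editing sites (e.g. \code{"nad7_C789"}).
#' All sites on a transcript share its strand; transcript coordinates are
#' self-consistent within the run (a toy layout, not a real genome).
#'
#' @param n_mito number of mitochondrial sites.
#' @param n_plastid number of plastid sites.
#' @param n_transcripts total number of transcripts to distribute sites
#'   over (split between organelles in proportion to their site counts).
#' @param seed integer seed; identical arguments give identical annotations.
#' @param tx_length toy transcript length in nt (sites are placed away from
#'   the ends so reads can anchor on both sides).
#'
#' @return A \code{data.frame} with columns \code{site_id},
#'   \code{transcript}, \code{organelle} (\code{"mito"} or
#'   \code{"plastid"}), \code{complex_group}, \code{strand},
#'   \code{tx_position} (1-based position in the transcript) and
#'   \code{genome_position} (1-based position on the toy reference).
#' @examples
#' sites <- gen_sites(576, 36, n_transcripts = 24, seed = 1)
#' table(sites$organelle)
#' @export
gen_sites <- function(n_mito, n_plastid, n_transcripts = 24, seed = 1,
                      tx_length = 1500L) {
  if (n_mito < 0 || n_plastid < 0) {
    abort("site counts must be non-negative")
  }
  n_total <- n_mito + n_plastid
  empty <- data.frame(
    site_id = character(), transcript = character(),
    organelle = character(), complex_group = character(),
    strand = character(), tx_position = integer(),
    genome_position = integer(), stringsAsFactors = FALSE
  )
  if (n_total == 0L) {
    return(empty)
  }
  if (n_transcripts < 1) abort("n_transcripts must be >= 1")

  n_tx_mito <- if (n_mito == 0) 0L else
    max(1L, round_half_away(n_transcripts * n_mito / n_total))
  n_tx_plastid <- if (n_plastid == 0) 0L else
    max(1L, n_transcripts - n_tx_mito)

  with_seed(seed, {
    mito <- .gen_sites_one("mito", n_mito, n_tx_mito, .mito_tx_pool,
                           tx_length)
    plastid <- .gen_sites_one("plastid", n_plastid, n_tx_plastid,
                              .plastid_tx_pool, tx_length)
    out <- rbind(mito, plastid)
    rownames(out) <- NULL
    out
  })
}

.gen_sites_one <- function(organelle, n_sites, n_tx, pool, tx_length) {
  if (n_sites == 0L) {
    return(NULL)
  }
  tx_names <- if (n_tx <= length(pool)) pool[seq_len(n_tx)] else
    c(pool, paste0("orf", seq_len(n_tx - length(pool)) + 100L))
  # every transcript carries at least one site; the rest fall at random
  alloc <- rep(1L, n_tx)
  extra <- n_sites - n_tx
  if (extra < 0) {
    tx_names <- tx_names[seq_len(n_sites)]
    alloc <- rep(1L, n_sites)
    n_tx <- n_sites
    extra <- 0L
  }
  if (extra > 0) {
    more <- table(factor(sample.int(n_tx, extra, replace = TRUE),
                         levels = seq_len(n_tx)))
    alloc <- alloc + as.integer(more)
  }
  offset <- (seq_len(n_tx) - 1L) * (tx_length + 100L)
  strand <- sample(c("+", "-"), n_tx, replace = TRUE)
  rows <- lapply(seq_len(n_tx), function(i) {
    # keep sites off the transcript ends so flanking anchors always exist
    pos <- sort(sample(seq(50L, tx_length - 50L), alloc[i]))
    data.frame(
      site_id = paste0(tx_names[i], "_C", pos),
      transcript = tx_names[i],
      organelle = organelle,
      complex_group = .complex_group(tx_names[i]),
      strand = strand[i],
      tx_position = pos,
      genome_position = offset[i] + pos,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write / read a site annotation table
#'
#' Tab-separated, one row per site, columns as in \code{\link{gen_sites}}.
#' \code{write_sites_bed} exports the 0-based half-open BED representation
#' (one-base intervals at each C target).
#'
#' @param sites a site annotation \code{data.frame}.
#' @param path file path.
#' @return \code{read_sites} returns the annotation \code{data.frame}.
#' @export
write_sites <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "transcript", "organelle", "strand", "tx_position")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    abort("annotation is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(out$site_id)) abort("duplicate site_id in annotation")
  out
}

#' @rdname write_sites
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(
    chrom = sites$transcript,
    start = sites$tx_position - 1L, # BED is 0-based half-open
    end = sites$tx_position,
    name = sites$site_id,
    score = 0L,
    strand = sites$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
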