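# The sites x samples count container shared by all downstream stages.

#' Editing count matrix
#'
#' Container for per-site, per-sample (edited, unedited, other) read
#' counts. \code{edited} counts reads showing the edited base (T on the
#' transcript sense strand), \code{unedited} reads showing C, \code{other}
#' any other base (excluded from the extent denominator). The container is
#' always rectangular: cells with no data hold zero depth rather than
#' being dropped.
#'
#' @param edited,unedited,other integer matrices (sites x samples) with
#'   identical dimnames; \code{other} defaults to all-zero.
#' @param sites site annotation \code{data.frame} (rows matching the
#'   matrix row order).
#' @param design sample design \code{data.frame} (rows matching columns).
#' @return An object of class \code{editing_matrix}.
#' @export
editing_matrix <- function(edited, unedited, other = NULL, sites, design) {
  if (!identical(dim(edited), dim(unedited))) {
    abort("edited and unedited matrices must have identical dimensions")
  }
  if (is.null(other)) {
    other <- edited
    other[] <- 0L
  }
  if (any(edited < 0) || any(unedited < 0) || any(other < 0)) {
    abort("counts must be non-negative")
  }
  if (nrow(edited) != nrow(sites)) {
    abort("site annotation does not match matrix rows")
  }
  if (ncol(edited) != nrow(design)) {
    abort("design does not match matrix columns")
  }
  rownames(edited) <- rownames(unedited) <- rownames(other) <- sites$site_id
  colnames(edited) <- colnames(unedited) <- colnames(other) <-
    design$sample_id
  structure(
    list(edited = edited, unedited = unedited, other = other,
         sites = sites, design = design),
    class = "editing_matrix"
  )
}

#' @export
print.editing_matrix <- function(x, ...) {
  cat("editing_matrix:", nrow(x$edited), "sites x", ncol(x$edited),
      "samples\n")
  cat("per-sample median depth:",
      paste(apply(x$edited + x$unedited, 2, stats::median),
            collapse = " "), "\n")
  invisible(x)
}

#' Per-cell editing extents of a matrix
#'
#' @param x an \code{editing_matrix}.
#' @return Numeric matrix of extents edited/(edited+unedited); \code{NA}
#'   where the informative depth is zero.
#' @export
extents <- function(x) {
  stopifnot(inherits(x, "editing_matrix"))
  denom <- x$edited + x$unedited
  out <- x$edited / denom
  out[denom == 0] <- NA_real_
  out
}

#' Assemble an editing matrix from a long count table
#'
#' Takes rows of (site_id, sample_id, edited, unedited, other) and builds
#' the rectangular container. Cells absent from the input are recorded
#' explicitly as zero depth (and will be flagged \code{not_assayed} by the
#' classifier), never dropped silently; their number is reported in a
#' message and stored in the \code{incomplete_cells} attribute.
#'
#' @param counts long-format \code{data.frame} with columns
#'   \code{site_id}, \code{sample_id}, \code{edited}, \code{unedited} and
#'   optionally \code{other}.
#' @param design sample design table; every \code{sample_id} in
#'   \code{counts} must appear in it.
#' @param sites optional site annotation; defaults to a minimal annotation
#'   inferred from the site ids.
#' @return An \code{editing_matrix}.
#' @export
assemble_matrix <- function(counts, design, sites = NULL) {
  need <- c("site_id", "sample_id", "edited", "unedited")
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    abort("count table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(counts[c("site_id", "sample_id")])) {
    abort("duplicate (site_id, sample_id) rows in count table")
  }
  extra <- setdiff(unique(counts$sample_id), design$sample_id)
  if (length(extra)) {
    abort("samples absent from design: ", paste(extra, collapse = ", "))
  }
  if (is.null(sites)) {
    ids <- unique(counts$site_id)
    sites <- data.frame(
      site_id = ids,
      transcript = sub("_C[0-9]+$", "", ids),
      organelle = NA_character_,
      complex_group = NA_character_,
      strand = NA_character_,
      tx_position = suppressWarnings(
        as.integer(sub("^.*_C", "", ids))),
      genome_position = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  shape <- list(sites$site_id, design$sample_id)
  fill <- function(col) {
    m <- matrix(0L, nrow(sites), nrow(design), dimnames = shape)
    if (!is.null(counts[[col]])) {
      m[cbind(match(counts$site_id, sites$site_id),
              match(counts$sample_id, design$sample_id))] <-
        as.integer(counts[[col]])
    }
    m
  }
  em <- editing_matrix(fill("edited"), fill("unedited"), fill("other"),
                       sites, design)
  n_missing <- nrow(sites) * nrow(design) - nrow(counts)
  if (n_missing > 0) {
    message(n_missing, " (site, sample) cells absent from input; ",
            "recorded as zero depth")
  }
  attr(em, "incomplete_cells") <- n_missing
  em
}

#' Read and write editing count tables
#'
#' The native dialect is a long TSV with header columns \code{site_id},
#' \code{sample_id}, \code{edited}, \code{unedited}, \code{other}.
#' \code{read_count_table_wide} additionally accepts the wide layout used
#' by supplementary read-count datasets (one column pair per sample) via
#' an explicit column mapping.
#'
#' @param x an \code{editing_matrix} (for writing).
#' @param path file path.
#' @return \code{read_count_table} returns the long \code{data.frame};
#'   \code{write_count_table} returns \code{path} invisibly.
#' @export
write_count_table <- function(x, path) {
  stopifnot(inherits(x, "editing_matrix"))
  long <- as.data.frame(x)
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  out <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("site_id", "sample_id", "edited", "unedited")
  missing <- setdiff(need, names(out))
  if (length(missing)) {
    abort("count table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (is.null(out$other)) out$other <- 0L
  out
}

#' @rdname write_count_table
#' @param mapping named list: for each sample id, a character vector of
#'   the two (or three) column names holding its edited, unedited (and
#'   optionally other) counts, in that order.
#' @param site_col name of the column holding site ids.
#' @export
read_count_table_wide <- function(path, mapping, site_col = "site_id") {
  wide <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!site_col %in% names(wide)) {
    abort("wide table has no column '", site_col, "'")
  }
  rows <- lapply(names(mapping), function(s) {
    cols <- mapping[[s]]
    if (!all(cols %in% names(wide))) {
      abort("mapped columns absent for sample ", s, ": ",
            paste(setdiff(cols, names(wide)), collapse = ", "))
    }
    data.frame(
      site_id = wide[[site_col]],
      sample_id = s,
      edited = as.integer(wide[[cols[1]]]),
      unedited = as.integer(wide[[cols[2]]]),
      other = if (length(cols) >= 3) as.integer(wide[[cols[3]]]) else 0L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' @export
as.data.frame.editing_matrix <- function(x, ...) {
  grid <- expand.grid(site_id = rownames(x$edited),
                      sample_id = colnames(x$edited),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(
    grid,
    edited = as.vector(x$edited),
    unedited = as.vector(x$unedited),
    other = as.vector(x$other),
    stringsAsFactors = FALSE
  )
}
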