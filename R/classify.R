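# Replicate-intersection classification of differential editing.
#
# A site is called increased (decreased) in the mutant only if EVERY
# wild-type-replicate x mutant-replicate 2x2 chi-square is significant at
# the Bonferroni nominal threshold AND the editing-extent difference
# reaches the effect floor. With two biological replicates per genotype
# this is the four-test rule; it deliberately trades power for a very low
# family-wise false-positive rate.

#' Classification test configuration
#'
#' @param alpha_family desired family-wise error rate (default 1e-3).
#' @param n_tests Bonferroni divisor; \code{NULL} (default) uses the
#'   number of assayed sites in the current run.
#' @param alpha_nominal per-test threshold; derived as
#'   \code{alpha_family / n_tests} unless overridden explicitly.
#' @param min_delta effect-size floor on the editing-extent difference
#'   (default 0.1).
#' @param min_depth minimum informative reads per sample at a site for it
#'   to be assayed (default 100; below it the site is \code{not_assayed}).
#' @param continuity Yates continuity correction flag (default FALSE).
#' @param delta_mode \code{"pooled"} (default; difference of extents of
#'   replicate-summed counts) or \code{"mean"} (difference of means of
#'   per-replicate extents).
#' @return A list of class \code{test_config}.
#' @export
test_config <- function(alpha_family = 1e-3, n_tests = NULL,
                        alpha_nominal = NULL, min_delta = 0.1,
                        min_depth = 100, continuity = FALSE,
                        delta_mode = c("pooled", "mean")) {
  if (alpha_family <= 0 || alpha_family >= 1) {
    abort("alpha_family must be in (0, 1)")
  }
  if (min_delta <= 0 || min_delta >= 1) abort("min_delta must be in (0, 1)")
  delta_mode <- match.arg(delta_mode)
  if (!is.null(n_tests) && is.null(alpha_nominal)) {
    alpha_nominal <- bonferroni_threshold(alpha_family, n_tests)
  }
  structure(
    list(alpha_family = alpha_family, n_tests = n_tests,
         alpha_nominal = alpha_nominal, min_delta = min_delta,
         min_depth = min_depth, continuity = continuity,
         delta_mode = delta_mode),
    class = "test_config"
  )
}

.resolve_alpha <- function(config, n_assayed) {
  config$alpha_nominal %||%
    bonferroni_threshold(config$alpha_family,
                         config$n_tests %||% max(1L, n_assayed))
}

#' Pairwise replicate p-values at one site
#'
#' One chi-square p-value for every (wild-type replicate, mutant
#' replicate) pair, in wild-type-major order: with two replicates per
#' genotype the result is the four p-values of the four-test rule, ordered
#' (wt1,m1), (wt1,m2), (wt2,m1), (wt2,m2).
#'
#' @param wt_edited,wt_unedited counts per wild-type replicate.
#' @param mut_edited,mut_unedited counts per mutant replicate.
#' @param config a \code{\link{test_config}} (only \code{continuity} is
#'   used here).
#' @return Named numeric vector of p-values.
#' @export
replicate_pvalues <- function(wt_edited, wt_unedited, mut_edited,
                              mut_unedited, config = test_config()) {
  if (length(wt_edited) < 1 || length(mut_edited) < 1) {
    abort("at least one replicate per genotype is required")
  }
  pairs <- expand.grid(m = seq_along(mut_edited),
                       w = seq_along(wt_edited))[, c("w", "m")]
  res <- chisq_2x2(wt_edited[pairs$w], wt_unedited[pairs$w],
                   mut_edited[pairs$m], mut_unedited[pairs$m],
                   continuity = config$continuity)
  setNames(res$p.value, paste0("p_wt", pairs$w, "_mut", pairs$m))
}

#' Editing-extent difference between genotypes at one site
#'
#' \code{mode = "pooled"} sums counts over replicates within each genotype
#' before taking extents; \code{mode = "mean"} averages per-replicate
#' extents. The sign is mutant minus wild-type.
#'
#' @inheritParams replicate_pvalues
#' @param mode \code{"pooled"} or \code{"mean"}.
#' @return Signed difference, or \code{NA} if either side has no
#'   informative reads.
#' @export
effect_delta <- function(wt_edited, wt_unedited, mut_edited, mut_unedited,
                         mode = c("pooled", "mean")) {
  mode <- match.arg(mode)
  if (mode == "pooled") {
    e_wt <- editing_extent(sum(wt_edited), sum(wt_unedited))
    e_mut <- editing_extent(sum(mut_edited), sum(mut_unedited))
  } else {
    e_wt <- mean(editing_extent(wt_edited, wt_unedited))
    e_mut <- mean(editing_extent(mut_edited, mut_unedited))
  }
  e_mut - e_wt
}

#' Classify one site from its p-values and delta
#'
#' \code{increased} iff all p-values fall below the nominal threshold and
#' delta >= min_delta; \code{decreased} iff all fall below and delta <=
#' -min_delta; otherwise \code{invariant}. The threshold comparison is
#' strict (a p exactly at the threshold fails).
#'
#' @param pvalues numeric vector of pairwise p-values (nonempty).
#' @param delta signed extent difference (mutant - wild-type).
#' @param config a \code{\link{test_config}} with a resolved
#'   \code{alpha_nominal} (or \code{n_tests} set).
#' @return One of \code{"increased"}, \code{"decreased"},
#'   \code{"invariant"}.
#' @export
classify_site <- function(pvalues, delta, config = test_config(n_tests = 612)) {
  if (length(pvalues) == 0) abort("pvalues must be nonempty")
  alpha <- config$alpha_nominal %||%
    abort("config must carry alpha_nominal or n_tests")
  if (is.na(delta)) return("invariant")
  sig <- all(pvalues < alpha)
  if (sig && delta >= config$min_delta) "increased"
  else if (sig && delta <= -config$min_delta) "decreased"
  else "invariant"
}

#' Classify every site of an editing matrix
#'
#' Applies the replicate-intersection rule to all sites for one
#' wild-type/mutant genotype pair. Sites where any replicate of either
#' genotype has fewer than \code{min_depth} informative reads are
#' \code{not_assayed} and excluded from the test family; the Bonferroni
#' divisor defaults to the number of assayed sites in this run.
#'
#' @param x an \code{\link{editing_matrix}}.
#' @param config a \code{\link{test_config}}.
#' @param wildtype,mutant genotype names; defaulted from the design roles
#'   when unambiguous.
#' @return A \code{data.frame} of class \code{site_classification} with
#'   columns \code{site_id}, \code{transcript}, \code{organelle},
#'   one p-value column per replicate pair (\code{p_wt1_mut1}, ...),
#'   \code{delta} and \code{category}; the resolved nominal threshold and
#'   genotype names are attached as attributes.
#' @export
classify_all <- function(x, config = test_config(), wildtype = NULL,
                         mutant = NULL) {
  stopifnot(inherits(x, "editing_matrix"))
  design <- x$design
  if (is.null(wildtype)) {
    wildtype <- unique(design$genotype[design$role == "wildtype"])
    if (length(wildtype) != 1) {
      abort("design must contain exactly one wildtype genotype ",
            "(or pass `wildtype`)")
    }
  }
  if (is.null(mutant)) {
    mutant <- unique(design$genotype[design$role == "mutant"])
    if (length(mutant) != 1) {
      abort("design holds ", length(mutant),
            " mutant genotypes; pass `mutant`")
    }
  }
  wt_cols <- design$sample_id[design$genotype == wildtype]
  mut_cols <- design$sample_id[design$genotype == mutant]
  if (length(wt_cols) == 0) abort("no wildtype samples in design")
  if (length(mut_cols) == 0) abort("no samples for mutant ", mutant)
  # deterministic replicate order regardless of design row order
  wt_cols <- wt_cols[order(design$replicate[match(wt_cols,
                                                  design$sample_id)])]
  mut_cols <- mut_cols[order(design$replicate[match(mut_cols,
                                                    design$sample_id)])]

  depth <- (x$edited + x$unedited)[, c(wt_cols, mut_cols), drop = FALSE]
  assayed <- rowSums(depth >= config$min_depth) == ncol(depth)
  alpha <- .resolve_alpha(config, sum(assayed))

  pairs <- expand.grid(m = seq_along(mut_cols), w = seq_along(wt_cols))
  pairs <- pairs[order(pairs$w, pairs$m), , drop = FALSE]
  pmat <- matrix(NA_real_, nrow(x$edited), nrow(pairs),
                 dimnames = list(rownames(x$edited),
                                 paste0("p_wt", pairs$w, "_mut", pairs$m)))
  for (k in seq_len(nrow(pairs))) {
    wc <- wt_cols[pairs$w[k]]
    mc <- mut_cols[pairs$m[k]]
    pmat[, k] <- chisq_2x2(x$edited[, wc], x$unedited[, wc],
                           x$edited[, mc], x$unedited[, mc],
                           continuity = config$continuity)$p.value
  }

  if (config$delta_mode == "pooled") {
    delta <- editing_extent(rowSums(x$edited[, mut_cols, drop = FALSE]),
                            rowSums(x$unedited[, mut_cols, drop = FALSE])) -
      editing_extent(rowSums(x$edited[, wt_cols, drop = FALSE]),
                     rowSums(x$unedited[, wt_cols, drop = FALSE]))
  } else {
    ext <- extents(x)
    delta <- rowMeans(ext[, mut_cols, drop = FALSE]) -
      rowMeans(ext[, wt_cols, drop = FALSE])
  }

  all_sig <- rowSums(pmat < alpha) == ncol(pmat)
  category <- rep("invariant", nrow(pmat))
  category[all_sig & !is.na(delta) & delta >= config$min_delta] <- "increased"
  category[all_sig & !is.na(delta) & delta <= -config$min_delta] <- "decreased"
  category[!assayed] <- "not_assayed"
  pmat[!assayed, ] <- NA_real_
  delta[!assayed] <- NA_real_

  out <- data.frame(
    site_id = x$sites$site_id,
    transcript = x$sites$transcript,
    organelle = x$sites$organelle,
    pmat,
    delta = delta,
    category = category,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("site_classification", "data.frame")
  attr(out, "alpha_nominal") <- alpha
  attr(out, "wildtype") <- wildtype
  attr(out, "mutant") <- mutant
  attr(out, "config") <- config
  out
}

#' Per-organelle category counts of a classification
#'
#' \code{not_assayed} sites are excluded from all category counts and
#' reported separately.
#'
#' @param cls a \code{site_classification}.
#' @return A \code{data.frame}: organelle x category counts plus assayed
#'   totals.
#' @export
classification_summary <- function(cls) {
  assayed <- cls[cls$category != "not_assayed", ]
  orgs <- unique(cls$organelle)
  out <- do.call(rbind, lapply(orgs, function(o) {
    sub <- assayed[assayed$organelle %in% o, ]
    data.frame(
      organelle = o,
      n_assayed = nrow(sub),
      increased = sum(sub$category == "increased"),
      decreased = sum(sub$category == "decreased"),
      invariant = sum(sub$category == "invariant"),
      not_assayed = sum(cls$organelle %in% o &
                          cls$category == "not_assayed"),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Intersect two site classifications
#'
#' The common-site view over two mutants: sites called in the same
#' direction in both are \code{common_increased} / \code{common_decreased};
#' sites affected in only one, or in opposite directions, are reported
#' separately.
#'
#' @param cls_a,cls_b \code{site_classification} tables over the same
#'   site universe.
#' @return A list with \code{table} (per-site joint categories) and
#'   \code{summary} (named counts: \code{common_increased},
#'   \code{common_decreased}, \code{a_only}, \code{b_only},
#'   \code{discordant}, \code{neither}).
#' @export
intersect_classifications <- function(cls_a, cls_b) {
  if (!setequal(cls_a$site_id, cls_b$site_id)) {
    abort("classifications cover different site sets")
  }
  b <- cls_b[match(cls_a$site_id, cls_b$site_id), ]
  ca <- cls_a$category
  cb <- b$category
  aff_a <- ca %in% c("increased", "decreased")
  aff_b <- cb %in% c("increased", "decreased")
  joint <- rep("neither", length(ca))
  joint[aff_a & !aff_b] <- "a_only"
  joint[!aff_a & aff_b] <- "b_only"
  joint[aff_a & aff_b & ca != cb] <- "discordant"
  joint[ca == "increased" & cb == "increased"] <- "common_increased"
  joint[ca == "decreased" & cb == "decreased"] <- "common_decreased"
  tab <- data.frame(
    site_id = cls_a$site_id,
    organelle = cls_a$organelle,
    category_a = ca,
    category_b = cb,
    joint = joint,
    stringsAsFactors = FALSE
  )
  lev <- c("common_increased", "common_decreased", "a_only", "b_only",
           "discordant", "neither")
  list(table = tab,
       summary = setNames(as.integer(table(factor(joint, levels = lev))),
                          lev))
}

#' Write a classification table as TSV
#'
#' @param cls a \code{site_classification}.
#' @param path output path.
#' @export
write_classification <- function(cls, path) {
  write.table(cls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
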