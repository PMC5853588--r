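# Binomial read-count simulation over a truth table.

#' Simulate per-site read counts from a truth table
#'
#' Draws, independently for every (site, sample) cell, the edited read
#' count from Binomial(depth, true extent of the sample's genotype); the
#' remainder of the depth is unedited. This matches the sampling model
#' assumed by the 2x2 chi-square used downstream. Two optional departures
#' are provided for robustness work: a beta-binomial dispersion (extents
#' jittered per cell around the truth) and a base-calling error rate that
#' diverts reads into the \code{other} category (excluded from the extent
#' denominator).
#'
#' @param truth a \code{truth_table} from \code{\link{gen_truth}}.
#' @param design sample design; every genotype must exist in the truth.
#' @param depth reads per site per sample: a scalar or a named vector by
#'   sample_id.
#' @param seed integer seed; identical inputs give identical counts.
#' @param dispersion beta-binomial overdispersion rho in [0, 1); 0 (the
#'   default) is pure binomial sampling.
#' @param error_rate probability a read shows a base that is neither C nor
#'   T on the sense strand (default 0).
#' @return An \code{\link{editing_matrix}}.
#' @examples
#' sites <- gen_sites(20, 0, 3, seed = 1)
#' tt <- gen_truth(sites, seed = 2)
#' em <- gen_counts(tt, design_from_truth(tt), depth = 500, seed = 3)
#' @export
gen_counts <- function(truth, design, depth = 1000, seed = 1,
                       dispersion = 0, error_rate = 0) {
  stopifnot(inherits(truth, "truth_table"))
  unknown <- setdiff(design$genotype, colnames(truth$extents))
  if (length(unknown)) {
    abort("genotypes absent from truth: ", paste(unknown, collapse = ", "))
  }
  if (any(depth < 0)) abort("depth must be non-negative")
  if (dispersion < 0 || dispersion >= 1) abort("dispersion must be in [0, 1)")

  n_sites <- nrow(truth$sites)
  n_samples <- nrow(design)
  if (is.null(names(depth))) {
    depth_by_sample <- rep(depth[1], n_samples)
  } else {
    depth_by_sample <- depth[design$sample_id]
    if (anyNA(depth_by_sample)) abort("depth missing for some samples")
  }

  with_seed(seed, {
    edited <- unedited <- other <-
      matrix(0L, n_sites, n_samples,
             dimnames = list(truth$sites$site_id, design$sample_id))
    for (j in seq_len(n_samples)) {
      p <- truth$extents[, design$genotype[j]]
      d <- depth_by_sample[j]
      if (d == 0) next
      if (dispersion > 0) {
        # beta-binomial: rho = 1/(a+b+1); degenerate p stays degenerate
        s <- (1 - dispersion) / dispersion
        jitter <- p > 0 & p < 1
        p[jitter] <- rbeta(sum(jitter), p[jitter] * s, (1 - p[jitter]) * s)
      }
      n_other <- if (error_rate > 0) {
        rbinom(n_sites, d, error_rate)
      } else {
        integer(n_sites)
      }
      e <- rbinom(n_sites, d - n_other, p)
      edited[, j] <- as.integer(e)
      unedited[, j] <- as.integer(d - n_other - e)
      other[, j] <- as.integer(n_other)
    }
    em <- editing_matrix(edited, unedited, other, truth$sites, design)
    attr(em, "seed") <- seed
    em
  })
}
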