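# Ground-truth editing extents per genotype for the synthetic study.

#' Generate a ground-truth table of editing extents
#'
#' Assigns every site a wild-type editing extent and an effect class
#' relative to wild-type (\code{increased}, \code{decreased} or
#' \code{invariant}), then derives mutant extents as wild-type plus a
#' signed delta. All mutant genotypes listed in \code{mutants} share the
#' same truth (the study design this emulates compares two independent
#' knockout alleles of one factor). Effects are restricted to sites of
#' \code{effect_organelle}; sites of other organelles are invariant.
#'
#' Realised class counts are \code{round(frac * n)} with halves rounded
#' away from zero. For non-invariant sites the base extent is drawn so that
#' clipping to [0, 1] can never shrink the realised |delta| below its drawn
#' value; if no feasible base extent exists after a bounded number of
#' draws, generation fails rather than silently weakening the effect.
#'
#' @param sites site annotation from \code{\link{gen_sites}}.
#' @param base_extent_range range the wild-type extent is drawn from.
#' @param frac_increased,frac_decreased fraction of effect-organelle sites
#'   assigned to each non-invariant class (must sum to at most 1).
#' @param delta_range range of |delta| for non-invariant sites; the lower
#'   bound is the guaranteed minimum effect size (default 0.1).
#' @param seed integer seed.
#' @param mutants character vector of mutant genotype names.
#' @param wildtype wild-type genotype name.
#' @param effect_organelle organelle whose sites can carry effects
#'   (\code{"mito"} by default, \code{"all"} for no restriction).
#'
#' @return An object of class \code{truth_table}: a list with
#'   \code{sites}, \code{effect_class} (named by site), \code{delta_true}
#'   (signed, 0 for invariant), \code{extents} (sites x genotypes matrix)
#'   and \code{wildtype}/\code{mutants} names.
#' @examples
#' sites <- gen_sites(100, 0, 5, seed = 1)
#' tt <- gen_truth(sites, frac_increased = 0.14, frac_decreased = 0.03,
#'                 seed = 2)
#' table(tt$effect_class)
#' @export
gen_truth <- function(sites,
                      base_extent_range = c(0.2, 0.95),
                      frac_increased = 0.14,
                      frac_decreased = 0.03,
                      delta_range = c(0.1, 0.4),
                      seed = 1,
                      mutants = "mut",
                      wildtype = "WT",
                      effect_organelle = "mito") {
  if (frac_increased < 0 || frac_decreased < 0 ||
      frac_increased + frac_decreased > 1) {
    abort("effect fractions must be non-negative and sum to at most 1")
  }
  if (delta_range[1] <= 0 || delta_range[1] > delta_range[2]) {
    abort("delta_range must be increasing and positive")
  }
  n <- nrow(sites)
  eligible <- if (identical(effect_organelle, "all")) rep(TRUE, n) else
    sites$organelle == effect_organelle
  n_eff <- sum(eligible)
  n_inc <- as.integer(round_half_away(frac_increased * n_eff))
  n_dec <- as.integer(round_half_away(frac_decreased * n_eff))
  if (n_inc + n_dec > n_eff) abort("rounded class counts exceed site count")

  with_seed(seed, {
    cls <- rep("invariant", n)
    idx <- sample(which(eligible), n_inc + n_dec)
    cls[idx[seq_len(n_inc)]] <- "increased"
    if (n_dec > 0) cls[idx[n_inc + seq_len(n_dec)]] <- "decreased"

    delta <- numeric(n)
    nonin <- cls != "invariant"
    delta[nonin] <- runif(sum(nonin), delta_range[1], delta_range[2])
    delta[cls == "decreased"] <- -delta[cls == "decreased"]

    wt <- runif(n, base_extent_range[1], base_extent_range[2])
    # resample base extents where adding delta would leave [0,1]
    for (i in which(nonin)) {
      tries <- 0L
      while (wt[i] + delta[i] < 0 || wt[i] + delta[i] > 1) {
        wt[i] <- runif(1, base_extent_range[1], base_extent_range[2])
        tries <- tries + 1L
        if (tries > 100L) {
          abort("no feasible base extent for |delta| = ",
                format(abs(delta[i])), " within base_extent_range")
        }
      }
    }
    mut <- pmin(1, pmax(0, wt + delta))

    extents <- matrix(wt, nrow = n, ncol = 1L + length(mutants),
                      dimnames = list(sites$site_id, c(wildtype, mutants)))
    for (m in mutants) extents[, m] <- mut

    structure(
      list(
        sites = sites,
        effect_class = setNames(cls, sites$site_id),
        delta_true = setNames(delta, sites$site_id),
        extents = extents,
        wildtype = wildtype,
        mutants = mutants
      ),
      class = "truth_table"
    )
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat("truth_table:", nrow(x$sites), "sites x",
      ncol(x$extents), "genotypes\n")
  print(table(x$effect_class))
  invisible(x)
}

#' Add a transgenic genotype to a truth table
#'
#' Derives the true editing extent of a transgenic (complemented) line as
#' \code{E_T = E_M + restore * (E_WT - E_M)}: \code{restore = 1} restores
#' the wild-type level exactly, \code{restore > 1} models a transgressive
#' response to overexpression. \code{invariant_shift} optionally moves
#' sites that are invariant in the mutant (emulating the off-target
#' response of overexpression); it is applied additively and clipped.
#'
#' @param truth a \code{truth_table}.
#' @param name transgenic genotype name (e.g. \code{"T5"}).
#' @param background name of the mutant genotype the line was made in.
#' @param restore complementation fraction (scalar).
#' @param invariant_shift additive shift applied to mutant-invariant sites
#'   (default 0); negative values model the inhibitory overexpression
#'   response.
#' @param n_invariant_shifted how many invariant sites receive the shift
#'   (default all of them).
#' @param seed seed for choosing which invariant sites are shifted.
#' @return The extended \code{truth_table}; the new genotype is recorded in
#'   \code{$transgenics} with its background.
#' @export
add_transgenic_truth <- function(truth, name, background, restore = 1,
                                 invariant_shift = 0,
                                 n_invariant_shifted = NULL, seed = 1) {
  stopifnot(inherits(truth, "truth_table"))
  if (!background %in% colnames(truth$extents)) {
    abort("unknown background genotype: ", background)
  }
  e_wt <- truth$extents[, truth$wildtype]
  e_m <- truth$extents[, background]
  e_t <- e_m + restore * (e_wt - e_m)
  if (invariant_shift != 0) {
    inv <- which(truth$effect_class == "invariant")
    if (!is.null(n_invariant_shifted)) {
      inv <- with_seed(seed, sample(inv, min(n_invariant_shifted,
                                             length(inv))))
    }
    e_t[inv] <- e_t[inv] + invariant_shift
  }
  new_col <- matrix(pmin(1, pmax(0, e_t)), ncol = 1,
                    dimnames = list(rownames(truth$extents), name))
  truth$extents <- cbind(truth$extents, new_col)
  truth$transgenics <- rbind(
    truth$transgenics,
    data.frame(genotype = name, background = background,
               stringsAsFactors = FALSE)
  )
  truth
}

#' Build a sample design table
#'
#' One row per sequenced sample: genotype, replicate index, role and (for
#' transgenics) the background mutant. Sample ids are
#' \code{"<genotype>_<replicate>"}.
#'
#' @param genotypes character vector of genotype names (repeated per
#'   replicate).
#' @param n_replicates replicates per genotype (scalar or named vector;
#'   transgenic lines in this design are typically single plants).
#' @param roles named character vector mapping genotype to role
#'   (\code{wildtype}, \code{mutant} or \code{transgenic}).
#' @param backgrounds named character vector mapping transgenic genotypes
#'   to their background mutant (NA otherwise).
#' @return A \code{data.frame} with columns \code{sample_id},
#'   \code{genotype}, \code{replicate}, \code{role}, \code{background}.
#' @export
make_design <- function(genotypes, n_replicates = 2, roles,
                        backgrounds = NULL) {
  if (is.null(names(n_replicates))) {
    n_rep <- setNames(rep(n_replicates[1], length(genotypes)), genotypes)
  } else {
    n_rep <- n_replicates
  }
  rows <- lapply(genotypes, function(g) {
    k <- n_rep[[g]]
    data.frame(
      sample_id = paste0(g, "_", seq_len(k)),
      genotype = g,
      replicate = seq_len(k),
      role = unname(roles[[g]]),
      background = if (!is.null(backgrounds) && g %in% names(backgrounds))
        backgrounds[[g]] else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Design table for the emulated study layout
#'
#' Convenience wrapper: one wild-type and two mutant genotypes, two
#' biological replicates each, plus optional transgenic single plants (two
#' per background, as in a complementation assay).
#'
#' @param truth a \code{truth_table} (transgenics added with
#'   \code{\link{add_transgenic_truth}} are picked up automatically).
#' @return A design \code{data.frame} (see \code{\link{make_design}}).
#' @export
design_from_truth <- function(truth) {
  stopifnot(inherits(truth, "truth_table"))
  genotypes <- c(truth$wildtype, truth$mutants)
  roles <- setNames(c("wildtype", rep("mutant", length(truth$mutants))),
                    genotypes)
  n_rep <- setNames(rep(2L, length(genotypes)), genotypes)
  backgrounds <- NULL
  if (!is.null(truth$transgenics)) {
    tg <- truth$transgenics$genotype
    genotypes <- c(genotypes, tg)
    roles <- c(roles, setNames(rep("transgenic", length(tg)), tg))
    n_rep <- c(n_rep, setNames(rep(1L, length(tg)), tg))
    backgrounds <- setNames(truth$transgenics$background, tg)
  }
  make_design(genotypes, n_rep, roles, backgrounds)
}
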