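# Transgenic rescue analysis: per-site significance versus the background
# mutant, expected-direction logic, the normalized complementation-effect
# statistic, the both/one/neither partition and the response of
# mutant-invariant sites to overexpression.

#' Expected direction of rescue at a differentially edited site
#'
#' A site whose editing extent increased in the mutant is expected to
#' decrease back in a complemented transgenic line, and vice versa.
#'
#' @param mutant_category \code{"increased"} or \code{"decreased"}.
#' @return \code{"decrease"} or \code{"increase"}.
#' @export
expected_direction <- function(mutant_category) {
  if (!all(mutant_category %in% c("increased", "decreased"))) {
    abort("expected_direction is defined only for affected sites")
  }
  ifelse(mutant_category == "increased", "decrease", "increase")
}

#' Complementation effect
#'
#' Normalizes the editing-extent change achieved by the transgene to the
#' change caused by the mutation:
#' \deqn{CE = (E_T - E_M) / (E_{WT} - E_M)}
#' CE = 1 is full restoration of the wild-type level, 0 no response, and
#' CE > 1 a transgressive response (overshooting wild-type, typical under
#' strong-promoter overexpression). Undefined where wild-type and mutant
#' extents are equal (the site was not differentially edited).
#'
#' @param e_t,e_m,e_wt editing extents of transgenic, mutant and wild-type
#'   (vectorised).
#' @return Numeric vector of CE values; \code{NA} where
#'   \code{e_wt == e_m}.
#' @examples
#' complementation_effect(0.8, 0.4, 0.8) # 1: full complementation
#' complementation_effect(0.9, 0.4, 0.8) # 1.25: transgressive
#' @export
complementation_effect <- function(e_t, e_m, e_wt) {
  out <- (e_t - e_m) / (e_wt - e_m)
  out[e_wt == e_m] <- NA_real_
  out
}

#' Test every site of a transgenic line against its background mutant
#'
#' Each transgenic plant is a single sample compared against every
#' biological replicate of its background mutant: one 2x2 chi-square per
#' (transgenic, mutant replicate) pair, all of which must fall below the
#' nominal threshold, plus the effect floor |delta_T| >= min_delta, where
#' delta_T = extent(transgenic) - extent(pooled mutant). \code{responded}
#' additionally requires the change to lie in the expected direction for
#' the site's mutant-vs-wild-type category.
#'
#' @param x an \code{\link{editing_matrix}} containing the transgenic,
#'   its background mutant and the wild-type samples.
#' @param mutant_class \code{site_classification} of the background
#'   mutant versus wild-type (from \code{\link{classify_all}}).
#' @param transgenic transgenic genotype name (single sample).
#' @param background background mutant genotype; defaulted from the
#'   design's \code{background} column.
#' @param config a \code{\link{test_config}}; the Bonferroni divisor
#'   defaults to the number of sites assayed here.
#' @return A \code{data.frame} of class \code{complementation_records}:
#'   per site, the pairwise p-values, \code{delta_t},
#'   \code{expected_direction} (NA for mutant-invariant sites),
#'   \code{significant}, \code{responded} and \code{ce} (complementation
#'   effect, computed from pooled extents).
#' @export
transgenic_site_test <- function(x, mutant_class, transgenic,
                                 background = NULL,
                                 config = test_config()) {
  stopifnot(inherits(x, "editing_matrix"))
  design <- x$design
  if (is.null(background)) {
    background <- design$background[design$genotype == transgenic][1]
    if (is.na(background)) {
      abort("no background recorded for ", transgenic,
            "; pass `background`")
    }
  }
  t_col <- design$sample_id[design$genotype == transgenic]
  if (length(t_col) != 1) {
    abort("expected exactly one sample for transgenic ", transgenic)
  }
  m_cols <- design$sample_id[design$genotype == background]
  if (length(m_cols) == 0) abort("no samples for background ", background)
  wildtype <- attr(mutant_class, "wildtype")
  wt_cols <- design$sample_id[design$genotype == wildtype]

  depth_t <- x$edited[, t_col] + x$unedited[, t_col]
  depth_m <- (x$edited + x$unedited)[, m_cols, drop = FALSE]
  assayed <- depth_t >= config$min_depth &
    rowSums(depth_m >= config$min_depth) == length(m_cols) &
    mutant_class$category[match(rownames(x$edited),
                                mutant_class$site_id)] != "not_assayed"
  alpha <- .resolve_alpha(config, sum(assayed))

  pmat <- matrix(NA_real_, nrow(x$edited), length(m_cols),
                 dimnames = list(rownames(x$edited),
                                 paste0("p_mut", seq_along(m_cols))))
  for (k in seq_along(m_cols)) {
    pmat[, k] <- chisq_2x2(x$edited[, t_col], x$unedited[, t_col],
                           x$edited[, m_cols[k]],
                           x$unedited[, m_cols[k]],
                           continuity = config$continuity)$p.value
  }

  e_t <- editing_extent(x$edited[, t_col], x$unedited[, t_col])
  e_m <- editing_extent(rowSums(x$edited[, m_cols, drop = FALSE]),
                        rowSums(x$unedited[, m_cols, drop = FALSE]))
  e_wt <- if (length(wt_cols)) {
    editing_extent(rowSums(x$edited[, wt_cols, drop = FALSE]),
                   rowSums(x$unedited[, wt_cols, drop = FALSE]))
  } else {
    rep(NA_real_, nrow(x$edited))
  }
  delta_t <- e_t - e_m

  mcat <- mutant_class$category[match(rownames(x$edited),
                                      mutant_class$site_id)]
  expd <- rep(NA_character_, length(mcat))
  aff <- mcat %in% c("increased", "decreased")
  expd[aff] <- expected_direction(mcat[aff])

  significant <- rowSums(pmat < alpha) == ncol(pmat) &
    !is.na(delta_t) & abs(delta_t) >= config$min_delta
  significant[!assayed] <- FALSE
  responded <- significant & !is.na(expd) &
    ((expd == "decrease" & delta_t <= -config$min_delta) |
       (expd == "increase" & delta_t >= config$min_delta))

  out <- data.frame(
    site_id = x$sites$site_id,
    transgenic_id = transgenic,
    organelle = x$sites$organelle,
    pmat,
    delta_t = delta_t,
    mutant_category = mcat,
    expected_direction = expd,
    assayed = assayed,
    significant = significant,
    responded = responded,
    ce = complementation_effect(e_t, e_m, e_wt),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  class(out) <- c("complementation_records", "data.frame")
  attr(out, "alpha_nominal") <- alpha
  attr(out, "background") <- background
  out
}

#' Run transgenic tests for several lines
#'
#' @param x an \code{\link{editing_matrix}}.
#' @param mutant_class classification of the shared background mutant.
#' @param transgenics character vector of transgenic genotype names.
#' @inheritParams transgenic_site_test
#' @return Named list of \code{complementation_records}, one per line.
#' @export
complement_all <- function(x, mutant_class, transgenics,
                           config = test_config()) {
  setNames(lapply(transgenics, function(tg) {
    transgenic_site_test(x, mutant_class, tg, config = config)
  }), transgenics)
}

#' Both/one/neither partition of mutant-affected sites
#'
#' For each site affected in the mutant, reports whether it responded (in
#' the expected direction) in both, only one, or neither of the two
#' transgenic lines of that background; fractions are printed percentages
#' (half away from zero). Per-direction panels (sites increased in the
#' mutant, sites decreased) and the combined totals are all emitted. The
#' at-least-one fraction (both plus only-one) is included since summaries
#' of this kind are often quoted inclusively.
#'
#' @param records list of exactly two \code{complementation_records} (one
#'   per transgenic line); with a single line a reduced
#'   responded/not-responded partition is returned with a warning.
#' @param mutant_class the background mutant's classification.
#' @return A \code{data.frame}: one row per panel (\code{increased},
#'   \code{decreased}, \code{combined}) with counts \code{n_sites},
#'   \code{both}, \code{only_one}, \code{neither} and percentage columns.
#' @export
complementation_summary <- function(records, mutant_class) {
  if (length(records) < 2) {
    warning("fewer than two transgenic lines: reduced partition")
    rec <- records[[1]]
    aff <- mutant_class$category %in% c("increased", "decreased")
    ids <- mutant_class$site_id[aff]
    resp <- rec$responded[match(ids, rec$site_id)]
    return(data.frame(panel = "combined", n_sites = length(ids),
                      responded = sum(resp), not_responded = sum(!resp)))
  }
  ra <- records[[1]]
  rb <- records[[2]]
  panel_rows <- lapply(
    list(increased = "increased", decreased = "decreased",
         combined = c("increased", "decreased")),
    function(cats) {
      ids <- mutant_class$site_id[mutant_class$category %in% cats]
      n <- length(ids)
      if (n == 0) {
        return(data.frame(n_sites = 0L, both = 0L, only_one = 0L,
                          neither = 0L, pct_both = NA_integer_,
                          pct_at_least_one = NA_integer_))
      }
      a <- ra$responded[match(ids, ra$site_id)]
      b <- rb$responded[match(ids, rb$site_id)]
      both <- sum(a & b)
      one <- sum(xor(a, b))
      data.frame(
        n_sites = n, both = both, only_one = one,
        neither = n - both - one,
        pct_both = round_percent(both, n),
        pct_at_least_one = round_percent(both + one, n)
      )
    })
  out <- cbind(panel = names(panel_rows), do.call(rbind, panel_rows))
  rownames(out) <- NULL
  out
}

#' Response of mutant-invariant sites in the transgenic lines
#'
#' Among sites that were invariant in the mutant (versus wild-type),
#' counts those significantly changed in the transgenics, by direction of
#' change and by whether one or both lines show it. Under overexpression
#' of an inhibitory factor the decreases are expected to dominate.
#'
#' @param records list of two \code{complementation_records}.
#' @param mutant_class the background mutant's classification.
#' @return A \code{data.frame} with rows \code{decrease}/\code{increase}
#'   and columns \code{both}, \code{only_one}, \code{any}.
#' @export
invariant_site_response <- function(records, mutant_class) {
  inv_ids <- mutant_class$site_id[mutant_class$category == "invariant"]
  dir_of <- function(rec) {
    d <- rep(NA_character_, length(inv_ids))
    i <- match(inv_ids, rec$site_id)
    sig <- rec$significant[i]
    d[sig & rec$delta_t[i] < 0] <- "decrease"
    d[sig & rec$delta_t[i] > 0] <- "increase"
    d
  }
  da <- dir_of(records[[1]])
  db <- dir_of(records[[2]])
  row <- function(dir) {
    both <- sum(!is.na(da) & !is.na(db) & da == dir & db == dir)
    any_ <- sum((!is.na(da) & da == dir) | (!is.na(db) & db == dir))
    data.frame(direction = dir, both = both, only_one = any_ - both,
               any = any_, stringsAsFactors = FALSE)
  }
  out <- rbind(row("decrease"), row("increase"))
  attr(out, "n_invariant") <- length(inv_ids)
  out
}
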