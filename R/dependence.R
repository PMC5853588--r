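# Cross-mutant dependence analysis and printed percentage roll-ups.

#' Integer percentage as printed in summaries
#'
#' round(100 * numerator / denominator) with halves rounded away from
#' zero, matching the convention of printed study summaries.
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return Integer percent.
#' @examples
#' round_percent(79, 576) # 14
#' @export
round_percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) abort("denominator must be positive")
  if (any(numerator < 0)) abort("numerator must be non-negative")
  as.integer(round_half_away(100 * numerator / denominator))
}

#' Cross-classification contingency table of two site classifications
#'
#' Cell (i, j) counts the sites in category i under classification A and
#' category j under B. Sites must be co-classified: both tables must
#' cover the same site universe, and every site must fall in exactly one
#' of the requested categories (sites \code{not_assayed} in either are
#' excluded first).
#'
#' @param cls_a,cls_b \code{site_classification} tables.
#' @param categories_a,categories_b category labels forming the rows and
#'   columns (default increased/decreased/invariant).
#' @param collapse_2x2 if TRUE, collapse to affected vs invariant in both
#'   dimensions.
#' @return An integer matrix with category dimnames.
#' @export
contingency_table <- function(cls_a, cls_b,
                              categories_a = c("increased", "decreased",
                                               "invariant"),
                              categories_b = categories_a,
                              collapse_2x2 = FALSE) {
  if (!setequal(cls_a$site_id, cls_b$site_id)) {
    abort("classifications cover different site sets")
  }
  if (anyDuplicated(categories_a) || anyDuplicated(categories_b)) {
    abort("categories must not overlap")
  }
  b <- cls_b[match(cls_a$site_id, cls_b$site_id), ]
  keep <- cls_a$category != "not_assayed" & b$category != "not_assayed"
  ca <- cls_a$category[keep]
  cb <- b$category[keep]
  bad <- !(ca %in% categories_a) | !(cb %in% categories_b)
  if (any(bad)) {
    abort("categories do not partition the co-classified sites")
  }
  if (collapse_2x2) {
    ca <- ifelse(ca == "invariant", "invariant", "affected")
    cb <- ifelse(cb == "invariant", "invariant", "affected")
    categories_a <- categories_b <- c("affected", "invariant")
  }
  table(factor(ca, levels = categories_a),
        factor(cb, levels = categories_b))
}

#' Chi-square test of independence with standardized residuals
#'
#' Pearson statistic sum((O - E)^2 / E) with (r-1)(c-1) degrees of
#' freedom; expected counts from the product of the margins. Rows or
#' columns with zero marginal total carry no information and are dropped
#' with a warning. Standardized residuals (O - E) / sqrt(E) localise
#' which cells drive a significant statistic. On a 2x2 table the
#' statistic coincides with \code{\link{chisq_2x2}} (no continuity
#' correction).
#'
#' @param tab a contingency matrix of counts.
#' @return A list of class \code{contingency_result}: \code{observed},
#'   \code{expected}, \code{statistic}, \code{df}, \code{p.value},
#'   \code{residuals}.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(unclass(tab))
  storage.mode(tab) <- "numeric"
  if (any(tab < 0)) abort("counts must be non-negative")
  rs <- rowSums(tab)
  cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("dropping zero-margin rows/columns")
    tab <- tab[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(tab)
    cs <- colSums(tab)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("need at least a 2x2 table after dropping empty margins")
  }
  n <- sum(tab)
  expected <- outer(rs, cs) / n
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  structure(
    list(observed = tab, expected = expected, statistic = stat, df = df,
         p.value = pchisq(stat, df = df, lower.tail = FALSE),
         residuals = (tab - expected) / sqrt(expected)),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("chi-square independence: X2 =", format(x$statistic, digits = 4),
      "df =", x$df, "p =", format(x$p.value, digits = 3), "\n")
  cat("standardized residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}

#' Per-transcript summary of affected sites
#'
#' For every transcript: number of assayed sites, sites increased and
#' decreased, and the printed percent affected; plus a roll-up by complex
#' group. Transcripts with mixed responses carry both direction counts.
#'
#' @param cls a \code{site_classification}.
#' @param sites site annotation supplying \code{transcript} and
#'   \code{complex_group} for every site.
#' @return A list with \code{by_transcript} and \code{by_complex}
#'   data.frames.
#' @export
per_transcript_summary <- function(cls, sites) {
  i <- match(cls$site_id, sites$site_id)
  if (anyNA(i)) {
    abort("sites absent from annotation: ",
          paste(head(cls$site_id[is.na(i)]), collapse = ", "))
  }
  df <- data.frame(
    transcript = sites$transcript[i],
    complex_group = sites$complex_group[i],
    category = cls$category,
    stringsAsFactors = FALSE
  )
  df <- df[df$category != "not_assayed", ]
  sum_by <- function(key) {
    agg <- function(val) {
      out <- aggregate(df$category, by = list(key = df[[key]]),
                       FUN = function(x) sum(x == val))
      setNames(out$x, out$key)
    }
    keys <- sort(unique(df[[key]]))
    n <- table(df[[key]])[keys]
    inc <- agg("increased")[keys]
    dec <- agg("decreased")[keys]
    out <- data.frame(
      key = keys,
      n_sites = as.integer(n),
      n_increased = as.integer(inc),
      n_decreased = as.integer(dec),
      pct_affected = round_percent(as.integer(inc) + as.integer(dec),
                                   as.integer(n)),
      stringsAsFactors = FALSE, row.names = NULL
    )
    names(out)[1] <- key
    out
  }
  list(by_transcript = sum_by("transcript"),
       by_complex = sum_by("complex_group"))
}
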