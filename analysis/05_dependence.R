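#!/usr/bin/env Rscript
# Stage 5 — cross-mutant dependence: cross-classify sites by their
# behaviour in the two mutants, test independence with the Pearson
# chi-square and localise the dependence with standardized residuals.
# With two alleles of the same factor the diagonal excess is extreme; the
# same machinery applies to classifications from different factors,
# where an off-diagonal excess (increased in one, decreased in the
# other) indicates opposed control of shared sites.

suppressMessages(library(orgedit))
out <- "results"
cls_a <- read.delim(file.path(out, "classification_mutA.tsv"),
                    stringsAsFactors = FALSE)
cls_b <- read.delim(file.path(out, "classification_mutB.tsv"),
                    stringsAsFactors = FALSE)

tab <- contingency_table(cls_a, cls_b)
res <- chisq_independence(tab)
cat("3x3 cross-classification (mutA rows, mutB columns):\n")
print(tab)
cat("\n")
print(res)

tab22 <- contingency_table(cls_a, cls_b, collapse_2x2 = TRUE)
res22 <- chisq_independence(tab22)
cat("\n2x2 collapse (affected vs invariant): X2 =",
    format(res22$statistic, digits = 4), ", p =",
    format(res22$p.value, digits = 3), "\n")

jsonlite::write_json(
  list(observed = as.data.frame.matrix(tab),
       statistic = res$statistic, df = res$df, p = res$p.value,
       residuals = as.data.frame.matrix(round(res$residuals, 2))),
  file.path(out, "dependence.json"), pretty = TRUE, auto_unbox = TRUE)
cat("\nWrote", file.path(out, "dependence.json"), "\n")
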