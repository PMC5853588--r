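# The replicate-intersection chi-square classifier.

test_that("bonferroni_threshold divides the family rate", {
  expect_equal(bonferroni_threshold(1e-3, 612), 1e-3 / 612)
  expect_equal(signif(bonferroni_threshold(1e-3, 612), 2), 1.6e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
  expect_error(bonferroni_threshold(0, 10), "in \\(0, 1\\)")
})

test_that("chisq_2x2 matches the closed-form Pearson statistic", {
  r <- chisq_2x2(900, 100, 600, 400)
  # 2000 * (900*400 - 600*100)^2 / (1000*1000*1500*500) = 240
  expect_equal(r$statistic, 240)
  expect_lt(r$p.value, 1.6e-6)

  expect_equal(chisq_2x2(50, 50, 50, 50)$statistic, 0)
  expect_equal(chisq_2x2(50, 50, 50, 50)$p.value, 1)

  # 20 * 100^2 / 10^4 = 20
  expect_equal(chisq_2x2(10, 0, 0, 10)$statistic, 20)

  # zero margin: no evidence, p = 1 by definition
  z <- chisq_2x2(0, 0, 5, 5)
  expect_equal(z$statistic, 0)
  expect_equal(z$p.value, 1)
})

test_that("chisq_2x2 agrees with independent oracles on random tables", {
  set.seed(101)
  n <- 1000
  tabs <- matrix(rpois(4 * n, lambda = 200) + 1L, ncol = 4)
  res <- chisq_2x2(tabs[, 1], tabs[, 2], tabs[, 3], tabs[, 4])
  # statistic: stats::chisq.test, uncorrected
  ref_stat <- vapply(seq_len(n), function(i) {
    unname(stats::chisq.test(matrix(tabs[i, ], 2, byrow = TRUE),
                             correct = FALSE)$statistic)
  }, numeric(1))
  expect_equal(res$statistic, ref_stat, tolerance = 1e-10)
  # tail probability: regularized incomplete gamma Q(1/2, x/2)
  ref_p <- stats::pgamma(res$statistic / 2, shape = 0.5,
                         lower.tail = FALSE)
  expect_equal(res$p.value, ref_p, tolerance = 1e-10)
})

test_that("chisq_2x2 statistic scales with counts and is row-symmetric", {
  set.seed(202)
  for (i in 1:50) {
    t4 <- rpois(4, 60) + 1
    s1 <- chisq_2x2(t4[1], t4[2], t4[3], t4[4])$statistic
    k <- sample(2:5, 1)
    sk <- chisq_2x2(k * t4[1], k * t4[2], k * t4[3], k * t4[4])$statistic
    expect_gte(sk, s1) # monotone in uniform scaling
    swap <- chisq_2x2(t4[3], t4[4], t4[1], t4[2])$statistic
    expect_equal(swap, s1)
  }
})

test_that("Yates correction shrinks the statistic", {
  plain <- chisq_2x2(30, 10, 20, 20)$statistic
  yates <- chisq_2x2(30, 10, 20, 20, continuity = TRUE)$statistic
  expect_lt(yates, plain)
})

test_that("replicate_pvalues emits one test per replicate pair", {
  p <- replicate_pvalues(c(900, 880), c(100, 120), c(600, 620),
                         c(400, 380))
  expect_length(p, 4)
  expect_named(p, c("p_wt1_mut1", "p_wt1_mut2", "p_wt2_mut1",
                    "p_wt2_mut2"))
  # identical counts everywhere: all p = 1
  p1 <- replicate_pvalues(c(50, 50), c(50, 50), c(50, 50), c(50, 50))
  expect_true(all(p1 == 1))
  expect_error(replicate_pvalues(numeric(0), numeric(0), 1, 1),
               "at least one replicate")
})

test_that("effect_delta computes pooled and mean differences", {
  # pooled: 1220/2000 - 1780/2000 = -0.28
  expect_equal(effect_delta(c(900, 880), c(100, 120), c(600, 620),
                            c(400, 380), mode = "pooled"), -0.28)
  # mean of per-replicate extents: equal here because depths are equal
  expect_equal(effect_delta(c(900, 880), c(100, 120), c(600, 620),
                            c(400, 380), mode = "mean"), -0.28)
  expect_equal(effect_delta(10, 10, 10, 10), 0)
  expect_true(is.na(effect_delta(0, 0, 5, 5)))
})

test_that("classify_site applies the all-tests-and-floor rule", {
  cfg <- test_config(n_tests = 612)
  expect_equal(classify_site(rep(1e-9, 4), 0.3, cfg), "increased")
  expect_equal(classify_site(rep(1e-9, 4), -0.3, cfg), "decreased")
  # effect floor: significant but small delta stays invariant
  expect_equal(classify_site(rep(1e-9, 4), 0.05, cfg), "invariant")
  # one failing test among four vetoes the call
  expect_equal(classify_site(c(1e-9, 1e-9, 1e-3, 1e-9), 0.3, cfg),
               "invariant")
  # threshold comparison is strict
  at <- cfg$alpha_nominal
  expect_equal(classify_site(rep(at, 4), 0.3, cfg), "invariant")
  expect_error(classify_site(numeric(0), 0.3, cfg), "nonempty")
})

test_that("classify_all recovers the simulated classes at depth", {
  study <- toy_study(n_mito = 200, n_plastid = 10, depth = 2000,
                     seed = 61, delta_range = c(0.3, 0.4))
  cls <- classify_all(study$matrix, test_config(), mutant = "mutA")
  truth_cls <- study$truth$effect_class[cls$site_id]
  nonin <- truth_cls != "invariant"
  # depth >= 1000 and |delta| >= 0.3: at least 95% of true effects called
  expect_gte(mean(cls$category[nonin] == truth_cls[nonin]), 0.95)
  # and no invariant site is called affected
  expect_true(all(cls$category[!nonin] == "invariant"))
})

test_that("classification is invariant to sample order within genotype", {
  study <- toy_study(n_mito = 40, n_plastid = 4, depth = 1500, seed = 71)
  em <- study$matrix
  perm <- rev(seq_len(ncol(em$edited)))
  em2 <- editing_matrix(em$edited[, perm], em$unedited[, perm],
                        em$other[, perm], em$sites, em$design[perm, ])
  c1 <- classify_all(em, test_config(), mutant = "mutA")
  c2 <- classify_all(em2, test_config(), mutant = "mutA")
  expect_equal(c1$category, c2$category)
  expect_equal(c1$delta, c2$delta)
})

test_that("low-depth sites are not_assayed and leave the test family", {
  study <- toy_study(n_mito = 30, n_plastid = 0, depth = 1000, seed = 81)
  em <- study$matrix
  em$edited[1, "mutA_1"] <- 0L
  em$unedited[1, "mutA_1"] <- 10L # below min_depth = 100
  cls <- classify_all(em, test_config(), mutant = "mutA")
  expect_equal(cls$category[1], "not_assayed")
  expect_true(all(is.na(cls$delta[1])))
  # the Bonferroni divisor follows the assayed count
  expect_equal(attr(cls, "alpha_nominal"), 1e-3 / 29)
  # summary excludes not_assayed from category counts
  s <- classification_summary(cls)
  expect_equal(s$n_assayed[s$organelle == "mito"], 29L)
  expect_equal(s$not_assayed[s$organelle == "mito"], 1L)
})

test_that("intersecting two mutants isolates common direction calls", {
  study <- toy_study(n_mito = 150, n_plastid = 10, depth = 2000, seed = 91,
                     delta_range = c(0.25, 0.4))
  cfg <- test_config()
  cls_a <- classify_all(study$matrix, cfg, mutant = "mutA")
  cls_b <- classify_all(study$matrix, cfg, mutant = "mutB")
  ix <- intersect_classifications(cls_a, cls_b)
  truth_cls <- study$truth$effect_class[cls_a$site_id]
  # the two mutants share the truth, so common counts track the truth
  expect_gte(ix$summary[["common_increased"]],
             0.9 * sum(truth_cls == "increased"))
  expect_gte(ix$summary[["common_decreased"]],
             0.9 * sum(truth_cls == "decreased"))
  expect_equal(ix$summary[["discordant"]], 0L)
  # manual single-site semantics
  a1 <- cls_a[1, ]; b1 <- cls_b[1, ]
  a1$category <- "increased"; b1$category <- "invariant"
  one <- intersect_classifications(a1, b1)
  expect_equal(unname(one$summary[["a_only"]]), 1L)
  bad <- cls_b[-1, ]
  expect_error(intersect_classifications(cls_a, bad), "different site sets")
})

test_that("under the null the four-test intersection is conservative", {
  # all-invariant truth: probability all four pairwise tests pass at
  # alpha_nominal is far below alpha_nominal itself
  sites <- gen_sites(300, 0, 5, seed = 1)
  tt <- gen_truth(sites, frac_increased = 0, frac_decreased = 0, seed = 2)
  design <- design_from_truth(tt)
  false_calls <- 0L
  for (b in 1:20) {
    em <- gen_counts(tt, design, depth = 1000, seed = 1000 + b)
    cls <- classify_all(em, test_config(alpha_nominal = 0.05,
                                        min_delta = 1e-9),
                        mutant = "mut")
    false_calls <- false_calls + sum(cls$category != "invariant")
  }
  # 6000 null sites tested at nominal 0.05 with the 4-test intersection:
  # the intersection rate is far below 0.05
  expect_lt(false_calls / 6000, 0.01)
})
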