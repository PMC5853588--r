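# Transgenic rescue: expected direction, complementation effect,
# both/one/neither partition, invariant-site response.

test_that("expected_direction inverts the mutant category", {
  expect_equal(expected_direction("increased"), "decrease")
  expect_equal(expected_direction("decreased"), "increase")
  expect_error(expected_direction("invariant"), "affected sites")
})

test_that("complementation_effect identities and transgressive flag", {
  # full complementation: E_T = E_WT
  expect_equal(complementation_effect(0.8, 0.4, 0.8), 1)
  # no response: E_T = E_M
  expect_equal(complementation_effect(0.4, 0.4, 0.8), 0)
  # transgressive overshoot
  expect_equal(complementation_effect(0.9, 0.4, 0.8), 1.25)
  expect_true(complementation_effect(0.9, 0.4, 0.8) > 1)
  expect_false(complementation_effect(0.8, 0.4, 0.8) > 1)
  # undefined where the site was not differentially edited
  expect_true(is.na(complementation_effect(0.5, 0.6, 0.6)))
})

test_that("complementation_effect identities hold over an extent grid", {
  grid <- expand.grid(e_wt = seq(0.05, 0.95, by = 0.15),
                      e_m = seq(0.05, 0.95, by = 0.15))
  grid <- grid[grid$e_wt != grid$e_m, ]
  expect_equal(complementation_effect(grid$e_wt, grid$e_m, grid$e_wt),
               rep(1, nrow(grid)))
  expect_equal(complementation_effect(grid$e_m, grid$e_m, grid$e_wt),
               rep(0, nrow(grid)))
  # affine invariance: shifting all three extents leaves CE unchanged
  keep <- grid$e_wt + 0.04 <= 1 & grid$e_m + 0.04 <= 1
  g <- grid[keep, ]
  e_t <- (g$e_wt + g$e_m) / 2
  expect_equal(complementation_effect(e_t + 0.04, g$e_m + 0.04,
                                      g$e_wt + 0.04),
               complementation_effect(e_t, g$e_m, g$e_wt))
})

test_that("responded requires significance AND the expected direction", {
  # one affected (increased) site; mutant extent 0.8, WT 0.4
  edited <- matrix(c(800, 790, 1600, 1590, 900),
                   nrow = 1,
                   dimnames = list("tx1_C10", NULL))
  unedited <- matrix(c(1200, 1210, 400, 410, 1100), nrow = 1)
  genotypes <- c("WT", "mut", "T1")
  design <- make_design(genotypes, c(WT = 2L, mut = 2L, T1 = 1L),
                        roles = c(WT = "wildtype", mut = "mutant",
                                  T1 = "transgenic"),
                        backgrounds = c(T1 = "mut"))
  sites <- data.frame(site_id = "tx1_C10", transcript = "tx1",
                      organelle = "mito", complex_group = "complex I",
                      strand = "+", tx_position = 10L,
                      genome_position = 10L, stringsAsFactors = FALSE)
  em <- editing_matrix(edited, unedited, sites = sites, design = design)
  cfg <- test_config(n_tests = 1)
  cls <- classify_all(em, cfg, wildtype = "WT", mutant = "mut")
  expect_equal(cls$category, "increased")

  # transgenic at 0.45: significant decrease in the expected direction
  rec <- transgenic_site_test(em, cls, "T1", config = cfg)
  expect_true(rec$significant)
  expect_equal(rec$expected_direction, "decrease")
  expect_true(rec$responded)
  expect_lt(rec$ce, 1.01)

  # transgenic identical to the mutant: all p = 1, no response
  em2 <- em
  em2$edited[, "T1_1"] <- 1600L
  em2$unedited[, "T1_1"] <- 400L
  rec2 <- transgenic_site_test(em2, cls, "T1", config = cfg)
  expect_true(all(rec2[, grep("^p_mut", names(rec2))] > 0.5))
  expect_false(rec2$responded)

  # significant but in the wrong direction (overshoot upward): no response
  em3 <- em
  em3$edited[, "T1_1"] <- 1900L
  em3$unedited[, "T1_1"] <- 100L
  rec3 <- transgenic_site_test(em3, cls, "T1", config = cfg)
  expect_true(rec3$significant)
  expect_false(rec3$responded)
})

test_that("full restoration yields a both-fraction near 100%", {
  study <- toy_study(n_mito = 150, n_plastid = 0, depth = 2000, seed = 111,
                     delta_range = c(0.25, 0.4), restore = 1)
  cfg <- test_config()
  cls <- classify_all(study$matrix, cfg, mutant = "mutA")
  recs <- complement_all(study$matrix, cls, c("T_mutA_1", "T_mutA_2"),
                         config = cfg)
  s <- complementation_summary(recs, cls)
  combined <- s[s$panel == "combined", ]
  expect_gte(combined$pct_both, 95)
  # CE concentrates near 1 for affected, responding sites
  aff <- recs[[1]][recs[[1]]$responded, ]
  expect_lt(abs(stats::median(aff$ce) - 1), 0.15)
})

test_that("complementation_summary partitions both/one/neither", {
  # synthetic records: 4 affected sites; responses (TT, TF, FT, FF)
  cls <- data.frame(
    site_id = paste0("s", 1:5),
    category = c("increased", "increased", "decreased", "decreased",
                 "invariant"),
    stringsAsFactors = FALSE
  )
  rec <- function(resp) {
    data.frame(site_id = paste0("s", 1:5), responded = c(resp, FALSE),
               stringsAsFactors = FALSE)
  }
  s <- complementation_summary(list(rec(c(TRUE, TRUE, FALSE, FALSE)),
                                    rec(c(TRUE, FALSE, TRUE, FALSE))),
                               cls)
  combined <- s[s$panel == "combined", ]
  expect_equal(combined$both, 1L)
  expect_equal(combined$only_one, 2L)
  expect_equal(combined$neither, 1L)
  expect_equal(combined$pct_both, 25L)
  expect_equal(combined$pct_at_least_one, 75L)
  # zero affected sites: empty summary without division
  none <- cls; none$category <- "invariant"
  s0 <- complementation_summary(list(rec(rep(FALSE, 4)),
                                     rec(rep(FALSE, 4))), none)
  expect_equal(s0[s0$panel == "combined", "n_sites"], 0L)
  expect_true(is.na(s0[s0$panel == "combined", "pct_both"]))
  # a single line degrades to responded/not with a warning
  expect_warning(s1 <- complementation_summary(
    list(rec(c(TRUE, TRUE, FALSE, FALSE))), cls), "fewer than two")
  expect_equal(s1$responded, 2L)
})

test_that("overexpression shifts of invariant sites are detected", {
  study <- toy_study(n_mito = 120, n_plastid = 0, depth = 2000, seed = 121,
                     delta_range = c(0.3, 0.4), restore = 1,
                     invariant_shift = -0.2, n_invariant_shifted = 50)
  cfg <- test_config()
  cls <- classify_all(study$matrix, cfg, mutant = "mutA")
  recs <- complement_all(study$matrix, cls, c("T_mutA_1", "T_mutA_2"),
                         config = cfg)
  inv <- invariant_site_response(recs, cls)
  dec <- inv[inv$direction == "decrease", ]
  # ~50 shifted invariant sites, all downward, detected in both lines
  expect_gte(dec$both, 40)
  expect_lte(abs(dec$any - 50), 8)
  expect_equal(sum(inv[inv$direction == "increase", "any"]), 0L)
})

test_that("transgenics identical to the mutant leave invariant sites quiet", {
  study <- toy_study(n_mito = 50, n_plastid = 0, depth = 1500, seed = 131,
                     restore = 0)
  cfg <- test_config()
  cls <- classify_all(study$matrix, cfg, mutant = "mutA")
  recs <- complement_all(study$matrix, cls, c("T_mutA_1", "T_mutA_2"),
                         config = cfg)
  inv <- invariant_site_response(recs, cls)
  expect_equal(sum(inv$any), 0L)
})
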