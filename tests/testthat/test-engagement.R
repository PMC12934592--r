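test_that("competition ratio and percent engagement follow the closed form", {
  expect_equal(engagement_ratio(100, 100), 1)
  expect_equal(engagement_ratio(100, 50), 2)
  expect_equal(percent_engagement(1), 0)
  expect_equal(percent_engagement(2), 50)
  expect_equal(percent_engagement(c(1, 2, 4)), c(0, 50, 75))
  expect_equal(percent_engagement(0.5), 0)    # noise-driven R < 1 clips to 0
  expect_error(percent_engagement(0), "positive")
  # saturation: treated signal at the floor gives near-complete engagement
  r <- engagement_ratio(100, 1e-6, floor = 1)
  expect_equal(r, 100)
  expect_gt(percent_engagement(r), 98)
})

test_that("percent engagement is monotone in R and scale-invariant", {
  r <- sort(runif(50, 1, 20))
  expect_true(all(diff(percent_engagement(r)) >= 0))
  g <- gen_engagement_table(40, doses = 20,
                            target_stoichiometry = c("20" = 50), cv = 0.1,
                            n_replicates = 3, seed = 7)
  scaled <- g$table
  scaled$sn <- scaled$sn * ifelse(scaled$replicate == 2, 3.7, 1)
  expect_equal(score_engagement(g$table)$R, score_engagement(scaled)$R)
})

test_that("vehicle signal at the floor marks a site unquantified", {
  tab <- tibble::tibble(protein = "P", position = 1L,
                        condition = c("DMSO", "SCA1_20uM"),
                        dose_uM = c(NA, 20), replicate = 1L,
                        sn = c(0.5, 80))
  sc <- score_engagement(tab, floor = 1)
  expect_false(sc$quantified)
  hits <- call_hits(sc)
  expect_equal(nrow(hits), 0L)   # unquantified sites never reach hit calling
})

test_that("hit calling requires reproducibility across replicates", {
  mk <- function(engagements) {
    sn_t <- 100 * (1 - engagements / 100)
    tibble::tibble(protein = "P", position = 1L,
                   condition = rep(c("DMSO", "SCA1_20uM"),
                                   each = length(engagements)),
                   dose_uM = rep(c(NA, 20), each = length(engagements)),
                   replicate = rep(seq_along(engagements), 2),
                   sn = c(rep(100, length(engagements)), sn_t))
  }
  hit <- call_hits(score_engagement(mk(c(60, 55, 58))), 50,
                   min_replicates = 2)
  expect_true(hit$is_hit)
  nohit <- call_hits(score_engagement(mk(c(60, 10, 12))), 50,
                     min_replicates = 2)
  expect_false(nohit$is_hit)     # one good replicate is not reproducible
  # default reproducibility demands ceil(2/3 n) replicates
  expect_true(call_hits(score_engagement(mk(c(60, 55, 10))))$reproducible)
  expect_false(call_hits(score_engagement(mk(c(60, 10, 10))))$reproducible)
  expect_error(call_hits(score_engagement(mk(c(60, 55))),
                         min_replicates = 5), "exceeds")
})

test_that("a planted engaged site is the unique top-ranked hit", {
  g <- gen_engagement_table(500, doses = c(5, 10, 20, 40),
                            target_stoichiometry =
                              c("5" = 20, "10" = 35, "20" = 50, "40" = 65),
                            cv = 0.1, n_replicates = 3, seed = 43)
  hits <- call_hits(score_engagement(g$table))
  hit_sites <- unique(hits[hits$is_hit, c("protein", "position")])
  expect_equal(nrow(hit_sites), 1L)
  expect_equal(hit_sites$protein, g$truth$target_site$protein)
  expect_equal(hit_sites$position, g$truth$target_site$position)
  sel <- selectivity_profile(hits, g$truth$target_site$protein,
                             g$truth$target_site$position)
  expect_equal(sel$rank, 1L)
  expect_equal(nrow(sel$off_targets), 0L)
  expect_error(selectivity_profile(hits, "NOPE", 1), "not present")
})

test_that("selectivity ranks a weaker second target behind the stronger", {
  base <- 100
  mk_site <- function(prot, pos, engagement) tibble::tibble(
    protein = prot, position = pos,
    condition = rep(c("DMSO", "SCA1_20uM"), each = 3),
    dose_uM = rep(c(NA, 20), each = 3), replicate = rep(1:3, 2),
    sn = c(rep(base, 3), rep(base * (1 - engagement / 100), 3)))
  tab <- dplyr::bind_rows(mk_site("A", 1L, 70), mk_site("B", 2L, 50),
                          mk_site("C", 3L, 5))
  hits <- call_hits(score_engagement(tab))
  sel <- selectivity_profile(hits, "B", 2L)
  expect_equal(sel$rank, 2L)
  expect_equal(nrow(sel$off_targets), 1L)
  expect_equal(sel$off_targets$protein, "A")
  # paralog roll-up: protein below cutoff everywhere reports not engaged
  byp <- sel$by_protein
  expect_false(byp$engaged[byp$protein == "C"])
  expect_true(all(byp$engaged[byp$protein %in% c("A", "B")]))
})

test_that("dose monotonicity detects concentration-dependent engagement", {
  tab <- tibble::tibble(protein = "P", position = 1L,
                        dose_uM = c(5, 10, 20, 40),
                        median_engagement = c(20, 45, 60, 75))
  m <- dose_monotonicity(tab, "P", 1L)
  expect_true(m$is_monotone)
  expect_equal(m$concordance, 1)
  tab2 <- tibble::tibble(protein = "P", position = 1L, dose_uM = c(5, 40),
                         median_engagement = c(60, 10))
  expect_false(dose_monotonicity(tab2, "P", 1L)$is_monotone)
  expect_error(dose_monotonicity(tab2[1, ], "P", 1L), ">= 2 doses")
  # noiseless planted curve is monotone for any tolerance >= 0
  g <- gen_engagement_table(10, doses = c(5, 10, 20, 40),
                            target_stoichiometry =
                              c("5" = 20, "10" = 35, "20" = 50, "40" = 65),
                            cv = 0, n_replicates = 2, seed = 3)
  hits <- call_hits(score_engagement(g$table))
  m2 <- dose_monotonicity(hits, g$truth$target_site$protein,
                          g$truth$target_site$position, tolerance = 0)
  expect_true(m2$is_monotone)
  expect_equal(m2$concordance, 1)
  expect_equal(m2$per_dose$median_engagement, c(20, 35, 50, 65),
               tolerance = 1e-10)
})
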