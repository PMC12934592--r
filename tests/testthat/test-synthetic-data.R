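test_that("ortholog generator honours its parameter contracts", {
  # identity case: same sequence in both species, conserved at equal positions
  p <- gen_ortholog_pair(20, identity = 1, n_conserved_cys = 2,
                         n_species_specific_cys = 0, indel_rate = 0, seed = 1)
  expect_identical(p$mouse, p$human)
  expect_equal(nrow(p$truth$conserved_pairs), 2L)
  expect_identical(p$truth$conserved_pairs[, 1], p$truth$conserved_pairs[, 2])

  # infeasible cysteine count and short length are explicit parameter errors
  expect_error(gen_ortholog_pair(9, 0.8, 4), ">= 10")
  expect_error(gen_ortholog_pair(12, 0.8, n_conserved_cys = 5),
               "too many cysteines")
})

test_that("emitted ortholog sequences are consistent with their truth", {
  for (s in c(3, 8, 21)) {
    p <- gen_ortholog_pair(60, identity = 0.8, n_conserved_cys = 3,
                           n_species_specific_cys = 1, indel_rate = 0.02,
                           seed = s)
    mouse <- strsplit(p$mouse, "")[[1]]
    human <- strsplit(p$human, "")[[1]]
    expect_identical(which(mouse == "C"), p$truth$mouse_cys_positions)
    expect_identical(which(human == "C"), p$truth$human_cys_positions)
    cp <- p$truth$conserved_pairs
    expect_true(all(diff(cp[, 1]) > 0))
    expect_true(all(mouse[cp[, 1]] == "C"))
    expect_true(all(human[cp[, 2]] == "C"))
    expect_true(all(cp[, 1] %in% p$truth$mouse_cys_positions))
    expect_true(all(cp[, 2] %in% p$truth$human_cys_positions))
    # exactly one species-specific cysteine without a partner
    expect_equal(length(p$truth$mouse_cys_positions) +
                   length(p$truth$human_cys_positions) - 2 * nrow(cp), 1L)
    # realised core identity close to requested (indels excluded by design)
    shared <- sum(mouse == strsplit(gen_ortholog_pair(
      60, 0.8, 3, 1, 0, seed = s)$human, "")[[1]])
    expect_lt(abs(shared / 60 - 0.8), 0.05 + 4 / 60)
  }
})

test_that("generators are byte-deterministic under a fixed seed", {
  expect_identical(gen_ortholog_pair(50, seed = 9),
                   gen_ortholog_pair(50, seed = 9))
  expect_identical(gen_oxidation_table(20, 4, 3, 2, seed = 9),
                   gen_oxidation_table(20, 4, 3, 2, seed = 9))
  expect_identical(gen_engagement_table(50, seed = 9,
                                        target_stoichiometry = c("20" = 50),
                                        doses = 20),
                   gen_engagement_table(50, seed = 9,
                                        target_stoichiometry = c("20" = 50),
                                        doses = 20))
  # different streams from one master seed are decoupled by name
  expect_false(substream_seed(1, "oxidation") == substream_seed(1, "domains"))
})

test_that("oxidation table has the stated shape, truth flags and clipping", {
  g <- gen_oxidation_table(n_sites = 500, n_conditions = 10,
                           n_replicates = 5, n_dynamic = 50,
                           dynamic_delta_range = c(15, 40), noise_sd = 2,
                           seed = 11)
  expect_equal(nrow(g$table), 500 * 10 * 5)
  expect_equal(sum(g$truth$is_dynamic), 50L)
  expect_true(all(g$table$percent_oxidation >= 0 &
                    g$table$percent_oxidation <= 100))
  expect_true(all(g$truth$true_delta[g$truth$is_dynamic] > 15 - 1e-9 &
                    g$truth$true_delta[g$truth$is_dynamic] < 40 + 1e-9))
  expect_true(all(g$truth$true_delta[!g$truth$is_dynamic] == 0))
  # truth flags mirror the generation threshold
  expect_identical(g$truth$is_dynamic, g$truth$true_delta > 10)
})

test_that("noiseless oxidation tables reproduce their truth exactly", {
  g <- gen_oxidation_table(10, 4, 5, 0, noise_sd = 0, seed = 3)
  per_site <- tapply(g$table$percent_oxidation,
                     paste(g$table$protein, g$table$position),
                     function(v) length(unique(v)))
  expect_true(all(per_site == 1))   # zero noise, zero signal: constant rows

  g2 <- gen_oxidation_table(10, 4, 5, 3, dynamic_delta_range = c(15, 30),
                            noise_sd = 0, seed = 4)
  prof <- redox_profiles(g2$table)
  m <- match(paste(prof$protein, prof$position),
             paste(g2$truth$protein, g2$truth$position))
  expect_equal(prof$delta, g2$truth$true_delta[m], tolerance = 1e-12)
})

test_that("oxidation generator rejects undetectable or degenerate designs", {
  expect_error(gen_oxidation_table(10, 1, 3, 0), "n_conditions")
  expect_error(gen_oxidation_table(10, 4, 3, 2,
                                   dynamic_delta_range = c(8, 20)),
               "undetectable")
  expect_error(gen_oxidation_table(10, 4, 3, 11), "exceeds")
})

test_that("domain intervals respect protein bounds", {
  prot <- tibble::tibble(protein = "X", length = 100)
  d <- gen_domain_table(prot, domains_per_protein = 1, seed = 2)
  expect_equal(nrow(d), 1L)
  expect_true(d$start >= 1 && d$start <= d$end && d$end <= 100)

  d3 <- gen_domain_table(tibble::tibble(protein = c("A", "B", "C"),
                                        length = c(50, 80, 120)),
                         domains_per_protein = 2, seed = 5)
  expect_equal(nrow(d3), 6L)
  expect_silent(validate_domains(d3))
  expect_error(gen_domain_table(tibble::tibble(protein = "Z", length = 0)),
               "non-positive length")
})

test_that("engagement screen construction matches its planted stoichiometry", {
  # noiseless single replicate: treated S/N is exactly half of vehicle
  g <- gen_engagement_table(5, doses = 20,
                            target_stoichiometry = c("20" = 50), cv = 0,
                            n_replicates = 1, seed = 1)
  w <- tidyr::pivot_wider(g$table, names_from = "condition",
                          values_from = "sn",
                          id_cols = c("protein", "position"))
  tgt <- w$protein == g$truth$target_site$protein &
    w$position == g$truth$target_site$position
  expect_equal(w$SCA1_20uM[tgt], w$DMSO[tgt] / 2)
  expect_equal(w$SCA1_20uM[!tgt], w$DMSO[!tgt])
  expect_true(all(g$table$sn > 0))

  g2 <- gen_engagement_table(200, doses = c(5, 10, 20, 40), cv = 0.1,
                             n_replicates = 3, seed = 13,
                             target_stoichiometry =
                               c("5" = 20, "10" = 35, "20" = 50, "40" = 65))
  expect_equal(nrow(g2$table), 200 * 5 * 3)   # sites x (DMSO + 4 doses) x reps
  expect_equal(nrow(g2$truth$background_sites), 199L)
  expect_true(all(diff(g2$truth$stoichiometry_by_dose) >= 0))

  expect_error(gen_engagement_table(5, doses = 20,
                                    target_stoichiometry = c("20" = 100)),
               "non-positive")
  expect_error(gen_engagement_table(5, doses = c(5, 20),
                                    target_stoichiometry =
                                      c("5" = 60, "20" = 10)),
               "non-decreasing")
})
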