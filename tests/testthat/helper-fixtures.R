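# Hand-written three-protein toy fixture. Small enough that every number
# in the expected compendium can be checked by eye:
#   P1: identical orthologs, Cys 3 and Cys 9 conserved; Cys 3 is dynamic
#       (liver 10 vs brain 40), Cys 9 stable (20 vs 25); SH2 domain [2,5]
#       covers human position 3.
#   P2: human carries a two-residue insertion before the conserved Cys, so
#       mouse Cys 3 maps to human Cys 5; its delta is exactly 10.0, which
#       is stable under the strict > threshold.
#   P3: the mouse Cys aligns to Ser in human -> no conserved cysteine.

toy_pairs <- function() {
  list(
    list(pair_id = "P1", mouse = "MACDEFGHCK", human = "MACDEFGHCK"),
    list(pair_id = "P2", mouse = "MKCLLLWYVD", human = "MKAACLLLWYVD"),
    list(pair_id = "P3", mouse = "MWCYYYHKLV", human = "MWSYYYHKLV")
  )
}

toy_oxidation <- function() {
  vals <- rbind(
    c("P1", 3, 10, 40),
    c("P1", 9, 20, 25),
    c("P2", 3, 15, 25)
  )
  tibble::tibble(
    protein = rep(vals[, 1], each = 4),
    position = as.integer(rep(vals[, 2], each = 4)),
    condition = rep(rep(c("liver_young", "brain_young"), each = 2), 3),
    replicate = rep(1:2, 6),
    percent_oxidation = as.numeric(t(vals[, 3:4]))[rep(1:6, each = 2)]
  )
}

toy_domains <- function() {
  tibble::tibble(protein = c("P1", "P2"),
                 domain_name = c("SH2", "PTP"),
                 start = c(2L, 8L), end = c(5L, 12L))
}

toy_class_lists <- function() {
  list(kinase = "P1", phosphatase = "P2")
}

toy_structures <- function() list(P1 = "2B3O")

run_toy_compendium <- function() {
  conserved <- dplyr::bind_rows(lapply(toy_pairs(), conserved_cysteines))
  profiles <- redox_profiles(toy_oxidation())
  build_compendium(conserved, profiles, toy_domains(), toy_class_lists(),
                   toy_structures())
}
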