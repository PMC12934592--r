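# Synthetic-data generators. Each generator plants a known signal and
# returns the emitted table together with a ground-truth record, so that
# every downstream stage can be scored against what was planted.
#
# Conventions: oxidation noise is additive Gaussian clipped to [0, 100];
# TMT signal-to-noise noise is multiplicative lognormal (S/N is positive
# and right-skewed); condition labels are opaque "tissue_age" strings.

AA_NO_CYS <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M",
               "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate one synthetic mouse/human ortholog pair with planted cysteines
#'
#' Builds a mouse sequence of `length` residues, then derives the human
#' ortholog by substituting a fixed fraction `1 - identity` of mutable
#' positions and applying insertions/deletions at rate `indel_rate`.
#' `n_conserved_cys` cysteines are planted at homologous positions in both
#' species (protected from mutation and indels); `n_species_specific_cys`
#' cysteines are planted in one species only (alternating, first in human)
#' and have no partner.
#'
#' @param length mouse sequence length in residues (>= 10).
#' @param identity target fractional identity of the homologous core.
#' @param n_conserved_cys number of cysteines planted in both species.
#' @param n_species_specific_cys cysteines planted in one species only.
#' @param indel_rate per-site probability of an insertion or deletion in
#'   the human sequence.
#' @param seed integer seed; identical seeds give byte-identical output.
#' @param pair_id identifier carried into the truth record and FASTA header.
#' @return list with `mouse` and `human` sequence strings and `truth`
#'   (`pair_id`, `mouse_cys_positions`, `human_cys_positions`,
#'   `conserved_pairs` as a two-column matrix).
#' @examples
#' p <- gen_ortholog_pair(60, identity = 0.8, n_conserved_cys = 3, seed = 7)
#' p$truth$conserved_pairs
#' @export
gen_ortholog_pair <- function(length, identity = 0.85, n_conserved_cys = 2,
                              n_species_specific_cys = 0, indel_rate = 0,
                              seed = 1, pair_id = "pair") {
  length <- check_count(length, "length", min = 1L)
  n_conserved_cys <- check_count(n_conserved_cys, "n_conserved_cys")
  n_species_specific_cys <- check_count(n_species_specific_cys,
                                        "n_species_specific_cys")
  identity <- check_fraction(identity, "identity")
  indel_rate <- check_fraction(indel_rate, "indel_rate")
  if (length < 10)
    stop_param("`length` must be >= 10 (got %d)", length)
  n_cys <- n_conserved_cys + n_species_specific_cys
  if (n_cys > length / 3)
    stop_param(paste0("too many cysteines for sequence length: ",
                      "%d + %d > %d/3"), n_conserved_cys,
               n_species_specific_cys, length)

  with_seed(seed, {
    mouse <- sample(AA_NO_CYS, length, replace = TRUE)
    cys_sites <- sort(sample.int(length, n_cys))
    conserved_at <- sort(sample(cys_sites, n_conserved_cys))
    specific_at <- setdiff(cys_sites, conserved_at)
    mouse[conserved_at] <- "C"

    # species-specific cysteines alternate species, human first
    specific_species <- rep_len(c("human", "mouse"),
                                max(length(specific_at), 1L))
    specific_species <- specific_species[seq_along(specific_at)]
    mouse[specific_at[specific_species == "mouse"]] <- "C"

    # substitute an exact count of mutable (non-planted) positions so the
    # realised core identity is deterministic given the parameters
    mutable <- setdiff(seq_len(length), cys_sites)
    n_sub <- round((1 - identity) * length)
    if (n_sub > length(mutable))
      stop_param("identity %.2f infeasible with %d planted cysteines",
                 identity, n_cys)
    sub_at <- if (n_sub > 0) sort(sample(mutable, n_sub)) else integer(0)

    human <- mouse
    human[specific_at] <- ifelse(specific_species == "human", "C",
                                 vapply(specific_at, function(i)
                                   sample(AA_NO_CYS, 1), character(1)))
    for (i in sub_at) human[i] <- sample(setdiff(AA_NO_CYS, mouse[i]), 1)

    # indels on the human side; planted sites are protected
    human_out <- character(0)
    map_h <- integer(length)   # mouse position -> human position (0 = deleted)
    for (i in seq_len(length)) {
      protected <- i %in% cys_sites
      if (!protected && indel_rate > 0 && runif(1) < indel_rate / 2) {
        map_h[i] <- 0L         # deletion
      } else {
        human_out <- c(human_out, human[i])
        map_h[i] <- length(human_out)
      }
      if (!protected && indel_rate > 0 && runif(1) < indel_rate / 2)
        human_out <- c(human_out, sample(AA_NO_CYS, 1))  # insertion
    }

    mouse_seq <- paste(mouse, collapse = "")
    human_seq <- paste(human_out, collapse = "")
    conserved_pairs <- cbind(mouse_pos = conserved_at,
                             human_pos = map_h[conserved_at])
    truth <- list(
      pair_id = pair_id,
      mouse_cys_positions = which(mouse == "C"),
      human_cys_positions = which(human_out == "C"),
      conserved_pairs = conserved_pairs
    )
    list(mouse = mouse_seq, human = human_seq, truth = truth)
  })
}

#' Write ortholog pairs to a pair of FASTA files
#'
#' @param pairs list of pairs from [gen_ortholog_pair()].
#' @param mouse_path,human_path output FASTA paths.
#' @return invisibly, the two paths.
#' @export
write_ortholog_fasta <- function(pairs, mouse_path, human_path) {
  ids <- vapply(pairs, function(p) p$truth$pair_id, character(1))
  m <- Biostrings::AAStringSet(setNames(
    vapply(pairs, `[[`, character(1), "mouse"), ids))
  h <- Biostrings::AAStringSet(setNames(
    vapply(pairs, `[[`, character(1), "human"), ids))
  Biostrings::writeXStringSet(m, mouse_path)
  Biostrings::writeXStringSet(h, human_path)
  invisible(c(mouse_path, human_path))
}

#' Generate a per-cysteine oxidation table with planted dynamic sites
#'
#' Emulates an in-vivo oxidation-stoichiometry resource: each site has a
#' true mean percent oxidation per condition; `n_dynamic` sites are planted
#' with a max-minus-min spread (delta) drawn uniformly from
#' `dynamic_delta_range`, the rest have identical means in every condition.
#' Observed values are true mean + Gaussian noise (sd `noise_sd`), clipped
#' to [0, 100].
#'
#' @param n_sites number of cysteine sites.
#' @param n_conditions number of tissue-by-age conditions (>= 2).
#' @param n_replicates replicates per site and condition.
#' @param n_dynamic number of planted dynamic sites (<= n_sites).
#' @param dynamic_delta_range `(lo, hi)` percent; `lo` must exceed
#'   `threshold`, otherwise the planted signal would be undetectable by
#'   construction.
#' @param noise_sd replicate noise standard deviation, percentage points.
#' @param threshold classification threshold the truth flags refer to
#'   (default 10).
#' @param seed integer seed.
#' @param sites optional tibble (`protein`, `position`) naming the sites;
#'   synthetic ids are generated when omitted.
#' @return list with `table` (tibble: protein, position, condition,
#'   replicate, percent_oxidation) and `truth` (tibble: protein, position,
#'   is_dynamic, true_delta, plus one `mean_<condition>` column per
#'   condition).
#' @export
gen_oxidation_table <- function(n_sites, n_conditions, n_replicates,
                                n_dynamic,
                                dynamic_delta_range = c(15, 40),
                                noise_sd = 2, threshold = 10, seed = 1,
                                sites = NULL) {
  n_sites <- check_count(n_sites, "n_sites", 1L)
  n_conditions <- check_count(n_conditions, "n_conditions")
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  n_dynamic <- check_count(n_dynamic, "n_dynamic")
  if (n_conditions < 2)
    stop_param("`n_conditions` must be >= 2: delta is undefined otherwise")
  if (n_dynamic > n_sites)
    stop_param("`n_dynamic` (%d) exceeds `n_sites` (%d)", n_dynamic, n_sites)
  lo <- dynamic_delta_range[1]; hi <- dynamic_delta_range[2]
  if (lo > hi) stop_param("dynamic_delta_range must be (lo, hi) with lo <= hi")
  if (n_dynamic > 0 && lo <= threshold)
    stop_param(paste0("dynamic_delta_range low end (%g) must exceed the ",
                      "classification threshold (%g): planted dynamic sites ",
                      "would be undetectable by construction"), lo, threshold)

  tissues <- c("liver", "brain", "heart", "kidney", "lung", "muscle",
               "fat", "spleen", "pancreas", "eye")
  conds <- paste(rep_len(tissues, n_conditions),
                 rep(c("young", "old"), each = length(tissues),
                     length.out = n_conditions),
                 sep = "_")
  conds <- make.unique(conds, sep = "")

  if (is.null(sites)) {
    sites <- tibble(protein = sprintf("PROT%04d", ceiling(seq_len(n_sites) / 4)),
                    position = 10L + 7L * ((seq_len(n_sites) - 1L) %% 4L) +
                      (seq_len(n_sites) - 1L) %/% 4L %% 3L)
  } else {
    sites <- as_tibble(sites)[, c("protein", "position")]
    if (nrow(sites) != n_sites)
      stop_param("`sites` has %d rows but n_sites = %d", nrow(sites), n_sites)
  }
  if (anyDuplicated(paste(sites$protein, sites$position)))
    stop_param("duplicate (protein, position) keys in `sites`")

  with_seed(seed, {
    dyn_idx <- if (n_dynamic > 0) sort(sample.int(n_sites, n_dynamic))
               else integer(0)
    is_dyn <- seq_len(n_sites) %in% dyn_idx

    true_means <- matrix(0, n_sites, n_conditions,
                         dimnames = list(NULL, conds))
    base <- runif(n_sites, 5, 55)
    for (s in seq_len(n_sites)) {
      if (is_dyn[s]) {
        delta <- runif(1, lo, hi)
        mn <- runif(1, 2, 95 - delta)
        means <- runif(n_conditions, mn, mn + delta)
        # pin the two extremes so the planted delta is exact
        i_min <- sample.int(n_conditions, 1)
        i_max <- sample(setdiff(seq_len(n_conditions), i_min), 1)
        means[i_min] <- mn
        means[i_max] <- mn + delta
        true_means[s, ] <- means
      } else {
        true_means[s, ] <- base[s]
      }
    }

    tab <- tibble(
      protein = rep(sites$protein, each = n_conditions * n_replicates),
      position = rep(sites$position, each = n_conditions * n_replicates),
      condition = rep(rep(conds, each = n_replicates), times = n_sites),
      replicate = rep(seq_len(n_replicates), times = n_sites * n_conditions)
    )
    mu <- as.vector(t(true_means))[rep(seq_len(n_sites * n_conditions),
                                       each = n_replicates)]
    obs <- mu + rnorm(nrow(tab), 0, noise_sd)
    tab$percent_oxidation <- pmin(100, pmax(0, obs))

    truth <- tibble(protein = sites$protein, position = sites$position,
                    is_dynamic = is_dyn,
                    true_delta = apply(true_means, 1, max) -
                      apply(true_means, 1, min))
    truth <- bind_cols(truth, as_tibble(true_means, .name_repair = "minimal")
                       %>% setNames(paste0("mean_", conds)))
    list(table = tab, truth = truth)
  })
}

#' Generate a Pfam-like domain-interval table
#'
#' Draws `domains_per_protein` intervals per protein, 1-based inclusive and
#' contained in `[1, length]`; intervals may overlap. Domain names are
#' sampled from a small vocabulary of common domain families.
#'
#' @param proteins tibble or data frame with `protein` and `length` columns.
#' @param domains_per_protein intervals drawn per protein.
#' @param seed integer seed.
#' @return tibble: protein, domain_name, start, end.
#' @export
gen_domain_table <- function(proteins, domains_per_protein = 2, seed = 1) {
  proteins <- as_tibble(proteins)
  if (!all(c("protein", "length") %in% names(proteins)))
    stop_param("`proteins` needs columns `protein` and `length`")
  if (any(proteins$length < 1))
    stop_param("protein of non-positive length: %s",
               proteins$protein[which(proteins$length < 1)[1]])
  domains_per_protein <- check_count(domains_per_protein,
                                     "domains_per_protein")
  vocab <- c("SH2", "PTP", "Pkinase", "zf-C2H2", "Trypsin", "TIR",
             "Death", "CARD", "Ig_like", "Fn3")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(proteins)), function(i) {
      L <- proteins$length[i]
      if (domains_per_protein == 0) return(NULL)
      start <- sample.int(L, domains_per_protein, replace = TRUE)
      end <- pmin(L, start + sample.int(max(1L, L %/% 2L),
                                        domains_per_protein, replace = TRUE))
      tibble(protein = proteins$protein[i],
             domain_name = sample(vocab, domains_per_protein, replace = TRUE),
             start = start, end = end)
    })
    bind_rows(out)
  })
}

#' Generate a TMT signal-to-noise table with one planted engaged site
#'
#' Emulates a competition chemoproteomics screen: every site has a
#' lognormal S/N baseline; vehicle (DMSO) and compound-treated channels are
#' the baseline times multiplicative lognormal noise with coefficient of
#' variation `cv`; the planted target's treated signal is additionally
#' scaled by `1 - stoichiometry/100` at each dose. Background sites have
#' true engagement zero.
#'
#' @param n_sites number of cysteine sites (target included).
#' @param doses numeric vector of compound doses (uM), ascending.
#' @param target_stoichiometry named mapping dose -> true percent
#'   engagement in `[0, 100)`, non-decreasing with dose; `NULL` for a null
#'   screen with no engaged site.
#' @param cv replicate coefficient of variation (fraction, >= 0).
#' @param n_replicates replicates per condition.
#' @param seed integer seed.
#' @param target_site list/row with `protein`, `position` naming the
#'   planted site (default SHP1 Cys102).
#' @param compound label used in condition strings (default "SCA1").
#' @return list with `table` (tibble: protein, position, condition,
#'   dose_uM, replicate, sn) and `truth` (list: `target_site`,
#'   `stoichiometry_by_dose`, `background_sites` tibble).
#' @export
gen_engagement_table <- function(n_sites, doses = c(5, 10, 20, 40),
                                 target_stoichiometry = NULL, cv = 0.1,
                                 n_replicates = 3, seed = 1,
                                 target_site = list(protein = "SHP1",
                                                    position = 102L),
                                 compound = "SCA1") {
  n_sites <- check_count(n_sites, "n_sites", 1L)
  n_replicates <- check_count(n_replicates, "n_replicates", 1L)
  if (!length(doses)) stop_param("`doses` must be non-empty")
  if (is.unsorted(doses)) stop_param("`doses` must be ascending")
  if (cv < 0) stop_param("`cv` must be >= 0")
  has_target <- !is.null(target_stoichiometry) &&
    length(target_stoichiometry) > 0
  if (has_target) {
    sto <- target_stoichiometry[match(as.character(doses),
                                      names(target_stoichiometry))]
    sto <- unname(sto)
    sto[is.na(sto)] <- 0
    if (any(sto >= 100))
      stop_param("target stoichiometry must be < 100%% (treated S/N would be non-positive)")
    if (any(sto < 0)) stop_param("target stoichiometry must be >= 0")
    if (is.unsorted(sto))
      stop_param("target stoichiometry must be non-decreasing with dose")
  } else sto <- rep(0, length(doses))

  prot <- sprintf("PRT%04d", ceiling(seq_len(n_sites) / 3))
  pos <- 15L + 11L * ((seq_len(n_sites) - 1L) %% 3L)
  if (has_target) {
    prot[1] <- target_site$protein
    pos[1] <- as.integer(target_site$position)
  }

  conds <- c("DMSO", sprintf("%s_%guM", compound, doses))
  dose_of <- c(NA_real_, doses)

  with_seed(seed, {
    baseline <- rlnorm(n_sites, meanlog = log(100), sdlog = 0.5)
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      noise <- function(k) rlnorm(k, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else noise <- function(k) rep(1, k)

    k <- length(conds)
    tab <- tibble(
      protein = rep(prot, each = k * n_replicates),
      position = rep(pos, each = k * n_replicates),
      condition = rep(rep(conds, each = n_replicates), times = n_sites),
      dose_uM = rep(rep(dose_of, each = n_replicates), times = n_sites),
      replicate = rep(seq_len(n_replicates), times = n_sites * k)
    )
    # surviving (unengaged) fraction per condition; background sites stay 1
    frac <- c(1, 1 - sto / 100)
    target_scale <- rep(frac, each = n_replicates)
    sn <- numeric(nrow(tab))
    for (s in seq_len(n_sites)) {
      rows <- ((s - 1) * k * n_replicates + 1):(s * k * n_replicates)
      fr <- if (s == 1 && has_target) target_scale else 1
      sn[rows] <- baseline[s] * fr * noise(length(rows))
    }
    tab$sn <- sn

    truth <- list(
      target_site = if (has_target)
        list(protein = prot[1], position = pos[1]) else NULL,
      stoichiometry_by_dose = setNames(sto, as.character(doses)),
      background_sites = tibble(protein = prot, position = pos)[
        if (has_target) -1 else seq_len(n_sites), ]
    )
    list(table = tab, truth = truth)
  })
}
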