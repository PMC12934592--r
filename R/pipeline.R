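# End-to-end orchestration: a single configuration drives simulation,
# alignment/mapping, redox classification, annotation and engagement
# scoring, writing provenance-stamped TSVs plus JSON summaries into a run
# directory. With the same configuration and seed, reruns are
# byte-identical.

#' Default pipeline configuration
#'
#' Returns the fully materialised configuration list for a simulate-mode
#' run. Every field can be overridden via [load_config()] or by editing
#' the returned list; unknown keys are rejected at validation.
#'
#' @param seed master seed; per-stage substreams are derived from it by
#'   stream name (see [substream_seed()]).
#' @return named list, see fields in the source.
#' @export
default_config <- function(seed = 1407) {
  list(
    mode = "simulate",
    seed = as.integer(seed),
    threshold = 10,               # percent; dynamic iff delta > threshold
    alignment = list(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                     free_end_gaps = FALSE),
    engagement = list(cutoff = 50, min_replicates = NULL, sn_floor = 1),
    simulation = list(
      n_pairs = 30, pair_length = 120, identity = 0.85,
      n_conserved_cys = 4, n_species_specific_cys = 1, indel_rate = 0.02,
      n_conditions = 20, n_replicates = 5, dynamic_fraction = 0.1,
      dynamic_delta_range = c(15, 40), noise_sd = 2,
      domains_per_protein = 2,
      screen_sites = 2000, doses = c(5, 10, 20, 40),
      target_stoichiometry = c("5" = 20, "10" = 35, "20" = 50, "40" = 65),
      cv = 0.1, screen_replicates = 3
    ),
    paths = list()                # real-data mode: input file paths
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file, fills unset fields from [default_config()], and
#' rejects unknown keys.
#'
#' @param path YAML file path.
#' @param seed optional master-seed override.
#' @return validated configuration list.
#' @export
load_config <- function(path, seed = NULL) {
  user <- yaml::read_yaml(path)
  config <- merge_config(default_config(), user, prefix = "")
  if (!is.null(seed)) config$seed <- as.integer(seed)
  validate_config(config)
}

merge_config <- function(base, user, prefix) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown))
    stop_param("unknown config key%s: %s", if (length(unknown) > 1) "s" else "",
               paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- merge_config(base[[k]], user[[k]],
                                prefix = paste0(prefix, k, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

validate_config <- function(config) {
  if (!config$mode %in% c("simulate", "real-data"))
    stop_param("config mode must be 'simulate' or 'real-data'")
  check_count(config$seed, "seed")
  if (config$threshold < 0 || config$threshold > 100)
    stop_param("threshold must be in [0, 100]")
  config
}

config_hash <- function(config) {
  substr(rlang::hash(config), 1, 12)
}

log_stage <- function(lines, stage, ...) {
  c(lines, sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full pipeline
#'
#' In simulate mode, generates ortholog pairs, oxidation, domain, class,
#' structure and screen tables from the configuration's simulation block,
#' then runs every analysis stage: conserved-cysteine mapping, redox
#' classification, compendium assembly, engagement scoring and selectivity.
#' Outputs are written under `outdir`; the configuration is echoed to
#' `config.yaml` and a truth-recovery report (conserved-pair recovery,
#' dynamic-site sensitivity/specificity, engagement bias) is written in
#' simulate mode.
#'
#' @param config configuration list from [default_config()] or
#'   [load_config()].
#' @param outdir run directory, created if needed.
#' @return invisibly, a list with the main tables and the recovery report.
#' @export
run_pipeline <- function(config = default_config(), outdir) {
  config <- validate_config(config)
  if (config$mode != "simulate")
    stop_param("real-data mode requires input paths for every stage; %s",
               "only simulate mode is wired end-to-end")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(config)
  seed <- config$seed
  sim <- config$simulation
  lines <- character(0)
  wt <- function(x, name) write_stage_tsv(x, file.path(outdir, name),
                                          seed = seed, config_hash = chash)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  ## stage: simulate ortholog pairs ------------------------------------
  pair_seed <- substream_seed(seed, "ortholog")
  pairs <- lapply(seq_len(sim$n_pairs), function(i)
    gen_ortholog_pair(sim$pair_length, sim$identity, sim$n_conserved_cys,
                      sim$n_species_specific_cys, sim$indel_rate,
                      seed = pair_seed + i,
                      pair_id = sprintf("PAIR%03d", i)))
  write_ortholog_fasta(pairs, file.path(outdir, "mouse.fasta"),
                       file.path(outdir, "human.fasta"))
  truth_pairs <- bind_rows(lapply(pairs, function(p)
    tibble(pair_id = p$truth$pair_id,
           mouse_position = p$truth$conserved_pairs[, "mouse_pos"],
           human_position = p$truth$conserved_pairs[, "human_pos"])))
  wt(truth_pairs, "truth_conserved.tsv")
  lines <- log_stage(lines, "simulate", "%d ortholog pairs, %d planted conserved cysteines",
                     sim$n_pairs, nrow(truth_pairs))

  ## stage: align and map conserved cysteines --------------------------
  al <- config$alignment
  conserved <- bind_rows(lapply(pairs, function(p)
    conserved_cysteines(list(pair_id = p$truth$pair_id, mouse = p$mouse,
                             human = p$human),
                        substitution_matrix = al$matrix,
                        gap_open = al$gap_open, gap_extend = al$gap_extend,
                        free_end_gaps = al$free_end_gaps)))
  wt(conserved, "conserved_cysteines.tsv")
  lines <- log_stage(lines, "align-map", "%d conserved cysteines called",
                     nrow(conserved))

  ## stage: oxidation table + redox classification ---------------------
  ox_sites <- conserved %>%
    select(protein = "pair_id", position = "mouse_position")
  ox <- gen_oxidation_table(
    n_sites = nrow(ox_sites), n_conditions = sim$n_conditions,
    n_replicates = sim$n_replicates,
    n_dynamic = round(sim$dynamic_fraction * nrow(ox_sites)),
    dynamic_delta_range = sim$dynamic_delta_range, noise_sd = sim$noise_sd,
    threshold = config$threshold, seed = substream_seed(seed, "oxidation"),
    sites = ox_sites)
  wt(ox$table, "oxidation.tsv")
  profiles <- redox_profiles(ox$table, threshold = config$threshold)
  wt(profiles, "redox_profiles.tsv")
  lines <- log_stage(lines, "classify", "%d sites profiled, %d dynamic at threshold %g",
                     nrow(profiles), sum(profiles$redox_class == "dynamic"),
                     config$threshold)

  ## stage: annotation tables + compendium ------------------------------
  prot_len <- tibble(protein = vapply(pairs, function(p) p$truth$pair_id,
                                      character(1)),
                     length = vapply(pairs, function(p) nchar(p$human),
                                     integer(1)))
  domains <- gen_domain_table(prot_len, sim$domains_per_protein,
                              seed = substream_seed(seed, "domains"))
  wt(domains, "domains.tsv")
  class_seed <- substream_seed(seed, "classes")
  class_lists <- with_seed(class_seed, {
    tags <- c("kinase", "phosphatase", "transcription_factor",
              "metabolic_enzyme")
    setNames(lapply(tags, function(t)
      sort(sample(prot_len$protein, max(1, nrow(prot_len) %/% 4)))), tags)
  })
  write_class_lists(class_lists, file.path(outdir, "protein_classes.tsv"))
  structures <- setNames(lapply(prot_len$protein, function(p)
    sprintf("AF-%s", p)), prot_len$protein)
  compendium <- build_compendium(conserved, profiles, domains, class_lists,
                                 structures, threshold = config$threshold)
  wt(compendium, "compendium.tsv")
  summ <- attr(compendium, "summary")
  jsonlite::write_json(summ, file.path(outdir, "compendium_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  lines <- log_stage(lines, "annotate",
                     "compendium %d rows; %d dynamic; %d dynamic on a domain",
                     summ$n_conserved, summ$n_dynamic,
                     summ$n_dynamic_with_domain)

  ## stage: engagement screen -------------------------------------------
  eng <- gen_engagement_table(
    n_sites = sim$screen_sites, doses = sim$doses,
    target_stoichiometry = sim$target_stoichiometry, cv = sim$cv,
    n_replicates = sim$screen_replicates,
    seed = substream_seed(seed, "engagement"))
  wt(eng$table, "screen_sn.tsv")
  scored <- score_engagement(eng$table, floor = config$engagement$sn_floor)
  hits <- call_hits(scored, engagement_cutoff = config$engagement$cutoff,
                    min_replicates = config$engagement$min_replicates)
  wt(scored, "engagement_scored.tsv")
  wt(hits, "engagement_hits.tsv")
  tgt <- eng$truth$target_site
  sel <- selectivity_profile(hits, tgt$protein, tgt$position)
  jsonlite::write_json(
    list(target = as.list(sel$target), rank = sel$rank,
         n_off_targets = nrow(sel$off_targets)),
    file.path(outdir, "selectivity.json"), auto_unbox = TRUE, pretty = TRUE)
  mono <- dose_monotonicity(hits, tgt$protein, tgt$position)
  lines <- log_stage(lines, "engage",
                     "%d sites screened; %d hit site(s); target rank %d; dose monotone: %s",
                     sim$screen_sites,
                     length(unique(paste(hits$protein, hits$position)[hits$is_hit])),
                     sel$rank, mono$is_monotone)

  ## truth recovery report ----------------------------------------------
  key <- function(d, p = "pair_id", q = "mouse_position")
    paste(d[[p]], d[[q]])
  tk <- paste(key(truth_pairs), truth_pairs$human_position)
  ck <- paste(key(conserved), conserved$human_position)
  recov_pairs <- length(intersect(tk, ck)) / length(union(tk, ck))
  truth_dyn <- ox$truth
  prof_key <- paste(profiles$protein, profiles$position)
  truth_key <- paste(truth_dyn$protein, truth_dyn$position)
  called_dyn <- profiles$redox_class[match(truth_key, prof_key)] == "dynamic"
  sens <- if (any(truth_dyn$is_dynamic))
    mean(called_dyn[truth_dyn$is_dynamic]) else NA_real_
  spec <- mean(!called_dyn[!truth_dyn$is_dynamic])
  top_dose <- as.character(max(sim$doses))
  est <- hits$median_engagement[hits$protein == tgt$protein &
                                  hits$position == tgt$position &
                                  !is.na(hits$dose_uM) &
                                  hits$dose_uM == max(sim$doses)]
  bias <- est - unname(sim$target_stoichiometry[top_dose])
  report <- list(conserved_recovery = recov_pairs,
                 dynamic_sensitivity = sens, dynamic_specificity = spec,
                 engagement_bias_top_dose = bias,
                 target_rank = sel$rank,
                 dose_monotone = mono$is_monotone)
  jsonlite::write_json(report, file.path(outdir, "truth_recovery.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  lines <- log_stage(lines, "recovery",
                     "conserved recovery %.3f; sensitivity %s; specificity %.3f",
                     recov_pairs, format(sens, digits = 3), spec)
  writeLines(lines, file.path(outdir, "pipeline.log"))
  invisible(list(conserved = conserved, profiles = profiles,
                 compendium = compendium, hits = hits, selectivity = sel,
                 truth = list(pairs = truth_pairs, oxidation = ox$truth,
                              engagement = eng$truth),
                 recovery = report, config = config))
}
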