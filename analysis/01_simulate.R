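#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs with planted ground truth.
#
# Emits, under results/sim/: mouse/human ortholog FASTA files, the planted
# conserved-cysteine truth, a per-cysteine oxidation table over 20
# tissue-by-age conditions (n = 5 replicates), Pfam-like domain intervals,
# protein-class membership lists, and a TMT S/N competition screen with one
# engaged site (SHP1 Cys102 at 20/35/50/65% stoichiometry over 5-40 uM).

suppressMessages(library(redoxmap))
suppressMessages(library(dplyr))

args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2]
                   else 1407)
outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
cfg <- default_config(seed)
sim <- cfg$simulation

pair_seed <- substream_seed(seed, "ortholog")
pairs <- lapply(seq_len(sim$n_pairs), function(i)
  gen_ortholog_pair(sim$pair_length, sim$identity, sim$n_conserved_cys,
                    sim$n_species_specific_cys, sim$indel_rate,
                    seed = pair_seed + i, pair_id = sprintf("PAIR%03d", i)))
write_ortholog_fasta(pairs, file.path(outdir, "mouse.fasta"),
                     file.path(outdir, "human.fasta"))
truth_pairs <- bind_rows(lapply(pairs, function(p)
  tibble::tibble(pair_id = p$truth$pair_id,
                 mouse_position = p$truth$conserved_pairs[, "mouse_pos"],
                 human_position = p$truth$conserved_pairs[, "human_pos"])))
write_stage_tsv(truth_pairs, file.path(outdir, "truth_conserved.tsv"),
                seed = seed)

# oxidation over the planted conserved mouse cysteines
sites <- truth_pairs %>% select(protein = pair_id, position = mouse_position)
ox <- gen_oxidation_table(nrow(sites), sim$n_conditions, sim$n_replicates,
                          n_dynamic = round(sim$dynamic_fraction * nrow(sites)),
                          dynamic_delta_range = sim$dynamic_delta_range,
                          noise_sd = sim$noise_sd, threshold = cfg$threshold,
                          seed = substream_seed(seed, "oxidation"),
                          sites = sites)
write_stage_tsv(ox$table, file.path(outdir, "oxidation.tsv"), seed = seed)
write_stage_tsv(ox$truth, file.path(outdir, "truth_oxidation.tsv"),
                seed = seed)

prot_len <- tibble::tibble(
  protein = vapply(pairs, function(p) p$truth$pair_id, character(1)),
  length = vapply(pairs, function(p) nchar(p$human), integer(1)))
domains <- gen_domain_table(prot_len, sim$domains_per_protein,
                            seed = substream_seed(seed, "domains"))
write_stage_tsv(domains, file.path(outdir, "domains.tsv"), seed = seed)

set.seed(substream_seed(seed, "classes"))
tags <- c("kinase", "phosphatase", "transcription_factor",
          "metabolic_enzyme")
class_lists <- setNames(lapply(tags, function(t)
  sort(sample(prot_len$protein, max(1, nrow(prot_len) %/% 4)))), tags)
write_class_lists(class_lists, file.path(outdir, "protein_classes.tsv"))

eng <- gen_engagement_table(sim$screen_sites, sim$doses,
                            sim$target_stoichiometry, sim$cv,
                            sim$screen_replicates,
                            seed = substream_seed(seed, "engagement"))
write_stage_tsv(eng$table, file.path(outdir, "screen_sn.tsv"), seed = seed)

cat(sprintf("simulated %d ortholog pairs (%d planted conserved cysteines),\n",
            sim$n_pairs, nrow(truth_pairs)))
cat(sprintf("oxidation table: %d rows (%d sites x %d conditions x %d reps; %d dynamic)\n",
            nrow(ox$table), nrow(sites), sim$n_conditions, sim$n_replicates,
            sum(ox$truth$is_dynamic)))
cat(sprintf("screen: %d sites, doses %s uM, target %s Cys%d\n",
            sim$screen_sites, paste(sim$doses, collapse = "/"),
            eng$truth$target_site$protein, eng$truth$target_site$position))
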