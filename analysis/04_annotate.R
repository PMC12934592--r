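#!/usr/bin/env Rscript
# Stage 4: assemble the compendium — conserved cysteines joined to redox
# class, containing domains, protein-class tags and structure ids — and
# report the headline counts plus the top dynamic sites per protein class.

suppressMessages(library(redoxmap))

conserved <- read_stage_tsv("results/conserved_cysteines.tsv")
profiles <- read_stage_tsv("results/redox_profiles.tsv")
domains <- read_stage_tsv("results/sim/domains.tsv")
class_lists <- read_class_lists("results/sim/protein_classes.tsv")
structures <- setNames(lapply(unique(conserved$pair_id),
                              function(p) sprintf("AF-%s", p)),
                       unique(conserved$pair_id))

compendium <- build_compendium(conserved, profiles, domains, class_lists,
                               structures)
write_stage_tsv(compendium, "results/compendium.tsv")
summ <- attr(compendium, "summary")
jsonlite::write_json(summ, "results/compendium_summary.json",
                     auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("compendium: %d conserved cysteines, %d dynamic (%.1f%%), %d dynamic on a domain\n",
            summ$n_conserved, summ$n_dynamic,
            100 * summ$n_dynamic / summ$n_conserved,
            summ$n_dynamic_with_domain))

for (cls in names(class_lists)) {
  top <- rank_top_sites(compendium, cls, k = 3)
  if (!nrow(top)) { cat(sprintf("%s: no dynamic sites\n", cls)); next }
  cat(sprintf("top dynamic %s sites: %s\n", cls,
              paste(sprintf("%s Cys%d (delta %.1f)", top$protein,
                            top$position, top$delta),
                    collapse = ", ")))
}
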