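#!/usr/bin/env Rscript
# Stage 3: per-cysteine redox profiles and stable/dynamic classification
# (dynamic = more than 10 percentage points between the highest- and
# lowest-oxidation conditions), scored against the planted truth.

suppressMessages(library(redoxmap))

ox <- read_stage_tsv("results/sim/oxidation.tsv")
profiles <- redox_profiles(ox, threshold = 10)
write_stage_tsv(profiles, "results/redox_profiles.tsv")

truth <- read_stage_tsv("results/sim/truth_oxidation.tsv")
called <- profiles$redox_class[match(paste(truth$protein, truth$position),
                                     paste(profiles$protein,
                                           profiles$position))] == "dynamic"
sens <- mean(called[truth$is_dynamic])
spec <- mean(!called[!truth$is_dynamic])

cat(sprintf("profiled %d sites over %d conditions: %d dynamic, %d stable\n",
            nrow(profiles), max(profiles$n_conditions),
            sum(profiles$redox_class == "dynamic"),
            sum(profiles$redox_class == "stable")))
cat(sprintf("dynamic-site sensitivity %.3f, specificity %.3f vs truth\n",
            sens, spec))
top <- profiles[order(-profiles$delta), ][1:5, ]
cat("largest deltas (site, delta, min->max condition):\n")
for (i in 1:5)
  cat(sprintf("  %s Cys%d  %5.1f  %s -> %s\n", top$protein[i],
              top$position[i], top$delta[i], top$min_condition[i],
              top$max_condition[i]))
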