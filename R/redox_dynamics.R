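# Per-cysteine dynamic-oxidation statistic and stable/dynamic
# classification. A site's delta is the difference between its maximum and
# minimum condition-mean oxidation; a site is dynamic when that difference
# exceeds the threshold (strictly), i.e. when it shows more than
# `threshold` percent difference between some two conditions.

#' Per-condition oxidation means for one site
#'
#' @param measurements tibble with `condition`, `percent_oxidation` (and
#'   optionally `replicate`) rows for a single site; `NA` values dropped.
#' @return tibble: condition, mean, sem (NA when n = 1), n. Conditions with
#'   no usable replicate are absent; empty input gives an empty tibble.
#' @examples
#' condition_means(tibble::tibble(condition = "liver",
#'                                percent_oxidation = c(10, 20, 30)))
#' @export
condition_means <- function(measurements) {
  measurements <- as_tibble(measurements)
  if (!nrow(measurements))
    return(tibble(condition = character(), mean = numeric(),
                  sem = numeric(), n = integer()))
  measurements %>%
    filter(!is.na(.data$percent_oxidation)) %>%
    group_by(.data$condition) %>%
    summarise(mean = mean(.data$percent_oxidation),
              sem = sd(.data$percent_oxidation) / sqrt(n()),
              n = n(), .groups = "drop")
}

#' Delta oxidation: max minus min of condition means
#'
#' Because the per-condition values are means, the maximum pairwise
#' difference between any two conditions equals max(means) - min(means);
#' both formulations coincide and the closed form is used.
#'
#' @param means named numeric vector or the tibble from
#'   [condition_means()].
#' @return delta in percentage points; 0 with a single condition.
#' @export
delta_oxidation <- function(means) {
  if (is.data.frame(means)) means <- means$mean
  means <- means[!is.na(means)]
  if (!length(means)) stop_param("no condition means: delta undefined")
  max(means) - min(means)
}

#' Classify a site as stable or dynamic
#'
#' Dynamic means strictly more than `threshold` percent difference between
#' some two conditions, so a delta of exactly `threshold` is stable. Sites
#' observed in fewer than two conditions are "unclassified" (no pair of
#' conditions to compare), not stable.
#'
#' @param delta non-negative delta oxidation, percentage points.
#' @param n_conditions number of conditions the site was observed in.
#' @param threshold classification threshold, percent (default 10).
#' @return one of `"stable"`, `"dynamic"`, `"unclassified"` (vectorised).
#' @export
classify_site <- function(delta, n_conditions, threshold = 10) {
  if (any(delta < 0, na.rm = TRUE))
    stop_param("negative delta: %g", min(delta))
  ifelse(n_conditions < 2, "unclassified",
         ifelse(delta > threshold, "dynamic", "stable"))
}

#' Redox profiles for every site of an oxidation table
#'
#' Groups an oxidation table by site, computes per-condition means, the
#' delta statistic, the extreme conditions with their s.e.m., and the
#' stable/dynamic class.
#'
#' @param oxidation tibble: protein, position, condition, replicate,
#'   percent_oxidation.
#' @param threshold classification threshold, percent (default 10).
#' @param collapse_ages if `TRUE`, strip the trailing `_<age>` token from
#'   condition labels and average ages within a tissue before computing
#'   delta; default keeps tissue-by-age conditions separate.
#' @return tibble, one row per site: protein, position, n_conditions,
#'   delta, min/max condition label, mean and sem, redox_class.
#' @export
redox_profiles <- function(oxidation, threshold = 10,
                           collapse_ages = FALSE) {
  oxidation <- as_tibble(oxidation)
  need <- c("protein", "position", "condition", "percent_oxidation")
  if (!all(need %in% names(oxidation)))
    stop_param("oxidation table needs columns: %s",
               paste(need, collapse = ", "))
  if (collapse_ages)
    oxidation$condition <- sub("_[^_]+$", "", oxidation$condition)
  prof <- oxidation %>%
    filter(!is.na(.data$percent_oxidation)) %>%
    group_by(.data$protein, .data$position, .data$condition) %>%
    summarise(mean = mean(.data$percent_oxidation),
              sem = sd(.data$percent_oxidation) / sqrt(n()),
              .groups = "drop_last") %>%
    summarise(n_conditions = n(),
              delta = max(.data$mean) - min(.data$mean),
              min_condition = .data$condition[which.min(.data$mean)],
              min_mean = min(.data$mean),
              min_sem = .data$sem[which.min(.data$mean)],
              max_condition = .data$condition[which.max(.data$mean)],
              max_mean = max(.data$mean),
              max_sem = .data$sem[which.max(.data$mean)],
              .groups = "drop")
  prof$redox_class <- classify_site(prof$delta, prof$n_conditions, threshold)
  arrange(prof, .data$protein, .data$position)
}

#' Minimum/maximum condition summary for one profile row
#'
#' Reports the extreme conditions' means with their replicate s.e.m. —
#' the per-site min/max bars of a top-sites figure.
#'
#' @param profile single row from [redox_profiles()].
#' @return list with `min` and `max`, each `(condition, mean, sem)`.
#' @export
summarize_min_max <- function(profile) {
  profile <- as_tibble(profile)
  if (nrow(profile) != 1L) stop_param("expected exactly one profile row")
  if (profile$n_conditions < 2)
    stop_param("min/max summary needs >= 2 conditions")
  list(min = list(condition = profile$min_condition,
                  mean = profile$min_mean, sem = profile$min_sem),
       max = list(condition = profile$max_condition,
                  mean = profile$max_mean, sem = profile$max_sem))
}

#' Top dynamic sites of a protein class
#'
#' Filters dynamic sites carrying a protein-class tag and returns the `k`
#' with the largest delta, ties broken by (protein, position)
#' lexicographically so the ranking is deterministic.
#'
#' @param profiles tibble from [redox_profiles()] with a `protein_classes`
#'   list- or `;`-separated character column (see
#'   [tag_protein_classes()]).
#' @param class_filter single class tag, e.g. `"kinase"`.
#' @param k maximum number of sites returned (default 10).
#' @return profile rows, delta descending.
#' @export
rank_top_sites <- function(profiles, class_filter, k = 10) {
  profiles <- as_tibble(profiles)
  # accept compendium naming (pair_id / mouse_position) as well
  if (!"protein" %in% names(profiles) && "pair_id" %in% names(profiles))
    profiles <- rename(profiles, protein = "pair_id")
  if (!"position" %in% names(profiles) &&
      "mouse_position" %in% names(profiles))
    profiles <- rename(profiles, position = "mouse_position")
  if (!"protein_classes" %in% names(profiles))
    stop_param("profiles lack a `protein_classes` column")
  tags <- if (is.list(profiles$protein_classes)) profiles$protein_classes
          else strsplit(profiles$protein_classes %||% "", ";", fixed = TRUE)
  known <- sort(unique(unlist(tags)))
  if (!class_filter %in% known)
    stop_param("unknown protein class '%s'; known classes: %s", class_filter,
               paste(known, collapse = ", "))
  keep <- vapply(tags, function(t) class_filter %in% t, logical(1))
  profiles[keep & profiles$redox_class == "dynamic", ] %>%
    arrange(desc(.data$delta), .data$protein, .data$position) %>%
    head(check_count(k, "k", 1L))
}
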