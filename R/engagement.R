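# Covalent-ligand engagement scoring from TMT signal-to-noise tables.
#
# For each cysteine site the competition ratio is
#     R = S/N(vehicle) / S/N(treated),
# and percent engagement (covalent occupancy) is derived as
#     100 * (1 - 1/R), clipped to [0, 100]
# — the standard stoichiometry conversion for competition chemoproteomics:
# a compound occupying a fraction f of a site suppresses the treated
# labeling signal to (1 - f) of vehicle, giving R = 1/(1 - f). S/N values
# below the floor (default 1) are floored before ratioing; sites whose
# vehicle signal sits at the floor are marked unquantified.

#' Competition engagement ratio
#'
#' @param sn_dmso,sn_treated signal-to-noise of the vehicle and treated
#'   channels (vectorised).
#' @param floor values below this are raised to it before ratioing
#'   (default 1).
#' @return `R = sn_dmso / sn_treated` after flooring.
#' @export
engagement_ratio <- function(sn_dmso, sn_treated, floor = 1) {
  if (any(is.na(sn_dmso)) || any(is.na(sn_treated)))
    stop_param("missing S/N value")
  pmax(sn_dmso, floor) / pmax(sn_treated, floor)
}

#' Percent engagement from a competition ratio
#'
#' @param R positive engagement ratio(s).
#' @return `100 * (1 - 1/R)` clipped to `[0, 100]`; R below 1 (apparent
#'   negative engagement from noise) clips to 0.
#' @examples
#' percent_engagement(c(1, 2, 4))   # 0, 50, 75
#' @export
percent_engagement <- function(R) {
  if (any(!is.finite(R) | R <= 0)) stop_param("R must be positive and finite")
  pmin(100, pmax(0, 100 * (1 - 1 / R)))
}

#' Per-replicate engagement of every site and dose
#'
#' Pairs each treated channel with the vehicle channel of the same
#' replicate, computes R and percent engagement per replicate, and flags
#' sites whose vehicle S/N sits at the floor as unquantified.
#'
#' @param sn_table tibble: protein, position, condition, dose_uM,
#'   replicate, sn; vehicle rows have `condition == "DMSO"`.
#' @param floor S/N floor (default 1).
#' @return tibble: protein, position, condition, dose_uM, replicate, R,
#'   percent_engagement, quantified.
#' @export
score_engagement <- function(sn_table, floor = 1) {
  sn_table <- as_tibble(sn_table)
  need <- c("protein", "position", "condition", "replicate", "sn")
  if (!all(need %in% names(sn_table)))
    stop_param("S/N table needs columns: %s", paste(need, collapse = ", "))
  if (!"dose_uM" %in% names(sn_table)) sn_table$dose_uM <- NA_real_
  if (any(sn_table$sn <= 0, na.rm = TRUE))
    stop_param("non-positive S/N value in input")
  veh <- sn_table %>% filter(.data$condition == "DMSO") %>%
    select(all_of(c("protein", "position", "replicate", "sn"))) %>%
    rename(sn_dmso = "sn")
  if (!nrow(veh)) stop_param("no DMSO (vehicle) rows in S/N table")
  trt <- sn_table %>% filter(.data$condition != "DMSO")
  out <- inner_join(trt, veh, by = c("protein", "position", "replicate"))
  out$R <- engagement_ratio(out$sn_dmso, out$sn, floor)
  out$percent_engagement <- percent_engagement(out$R)
  out$quantified <- pmax(out$sn_dmso, floor) > floor
  out %>% select(all_of(c("protein", "position", "condition", "dose_uM",
                          "replicate", "R", "percent_engagement",
                          "quantified")))
}

#' Reproducible hit calling across replicates
#'
#' A site is reproducible at a dose when its percent engagement reaches
#' `cutoff` in at least `min_replicates` replicates (default: ceiling of
#' two-thirds of the available replicates); it is a hit when reproducible
#' at any tested dose. The hit table is sorted by median percent
#' engagement, descending.
#'
#' @param scored tibble from [score_engagement()].
#' @param engagement_cutoff percent engagement threshold (default 50).
#' @param min_replicates replicates required at or above the cutoff;
#'   `NULL` for the two-thirds default.
#' @return tibble, one row per site and dose: protein, position, condition,
#'   dose_uM, n_replicates, n_above_cutoff, median_engagement, median_R,
#'   reproducible, is_hit (site-level flag, repeated across the site's
#'   doses).
#' @export
call_hits <- function(scored, engagement_cutoff = 50, min_replicates = NULL) {
  scored <- as_tibble(scored) %>% filter(.data$quantified)
  per_dose <- scored %>%
    group_by(.data$protein, .data$position, .data$condition, .data$dose_uM) %>%
    summarise(n_replicates = n(),
              n_above_cutoff = sum(.data$percent_engagement >=
                                     engagement_cutoff),
              median_engagement = median(.data$percent_engagement),
              median_R = median(.data$R), .groups = "drop")
  min_req <- function(n) if (is.null(min_replicates)) ceiling(2 * n / 3)
             else min_replicates
  if (!is.null(min_replicates) &&
      any(min_replicates > per_dose$n_replicates))
    stop_param("min_replicates (%d) exceeds available replicates (%d)",
               min_replicates, min(per_dose$n_replicates))
  per_dose$reproducible <- per_dose$n_above_cutoff >=
    min_req(per_dose$n_replicates)
  per_dose <- per_dose %>%
    group_by(.data$protein, .data$position) %>%
    mutate(is_hit = any(.data$reproducible)) %>%
    ungroup() %>%
    arrange(desc(.data$median_engagement), .data$protein, .data$position)
  per_dose
}

#' Selectivity profile of a target site in a screen
#'
#' Ranks the target among all scored sites by peak median engagement,
#' lists reproducible non-target sites engaged at least as strongly
#' (off-targets), and rolls engagement up per protein for paralog
#' comparison.
#'
#' @param hit_table tibble from [call_hits()].
#' @param target_protein,target_position the site of interest.
#' @return list: `target` (site summary), `rank` (1 = strongest),
#'   `off_targets` (tibble of reproducible sites with engagement >=
#'   target's, target excluded), `by_protein` (per-protein roll-up with an
#'   `engaged` flag: any reproducible site on the protein).
#' @export
selectivity_profile <- function(hit_table, target_protein, target_position) {
  per_site <- hit_table %>%
    group_by(.data$protein, .data$position) %>%
    summarise(peak_engagement = max(.data$median_engagement),
              reproducible = any(.data$reproducible),
              is_hit = first(.data$is_hit), .groups = "drop") %>%
    arrange(desc(.data$peak_engagement), .data$protein, .data$position)
  hit_row <- per_site$protein == target_protein &
    per_site$position == target_position
  if (!any(hit_row))
    stop_param("target %s:%s not present in the hit table", target_protein,
               target_position)
  rank <- which(hit_row)
  target <- per_site[hit_row, ]
  off <- per_site[!hit_row &
                    per_site$reproducible &
                    per_site$peak_engagement >= target$peak_engagement, ]
  by_protein <- per_site %>%
    group_by(.data$protein) %>%
    summarise(n_sites = n(),
              peak_engagement = max(.data$peak_engagement),
              engaged = any(.data$reproducible), .groups = "drop") %>%
    arrange(desc(.data$peak_engagement))
  list(target = target, rank = rank, off_targets = off,
       by_protein = by_protein)
}

#' Dose monotonicity of a site's engagement
#'
#' Concentration-dependent engagement is declared when the median percent
#' engagement never drops by more than `tolerance` percentage points as
#' the dose increases; concordance is the Spearman rank correlation
#' between dose and median engagement.
#'
#' @param hit_table tibble from [call_hits()] (or any tibble with
#'   `dose_uM` and `median_engagement`) restricted to one site, or a full
#'   table plus `protein`/`position` to select the site.
#' @param protein,position optional site selector.
#' @param tolerance allowed backward step, percentage points (default 5).
#' @return list: `is_monotone`, `concordance`, `per_dose` (dose-ordered
#'   tibble).
#' @export
dose_monotonicity <- function(hit_table, protein = NULL, position = NULL,
                              tolerance = 5) {
  tab <- as_tibble(hit_table)
  if (!is.null(protein))
    tab <- tab[tab$protein == protein & tab$position == position, ]
  tab <- tab[!is.na(tab$dose_uM), ] %>% arrange(.data$dose_uM)
  if (nrow(tab) < 2)
    stop_param("dose monotonicity needs >= 2 doses (got %d)", nrow(tab))
  e <- tab$median_engagement
  is_mono <- all(diff(e) >= -tolerance)
  conc <- suppressWarnings(cor(tab$dose_uM, e, method = "spearman"))
  list(is_monotone = is_mono, concordance = conc,
       per_dose = tab %>% select(all_of(c("dose_uM", "median_engagement"))))
}
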