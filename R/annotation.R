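# Functional annotation: domain-interval containment, protein-class
# tagging, and assembly of the compendium table joining conserved
# cysteines, redox profiles, domains, classes and structure identifiers.

#' Validate a domain-interval table
#'
#' Intervals are 1-based inclusive. Malformed rows (missing fields,
#' start > end, start < 1) raise a validation error at load time.
#'
#' @param domains tibble: protein, domain_name, start, end.
#' @return the validated tibble, invisibly usable downstream.
#' @export
validate_domains <- function(domains) {
  domains <- as_tibble(domains)
  need <- c("protein", "domain_name", "start", "end")
  if (!all(need %in% names(domains)))
    stop_param("domain table needs columns: %s", paste(need, collapse = ", "))
  bad <- which(is.na(domains$start) | is.na(domains$end) |
                 domains$start < 1 | domains$start > domains$end)
  if (length(bad))
    stop_param("malformed domain interval in row %d (%s: [%s, %s])", bad[1],
               domains$protein[bad[1]], domains$start[bad[1]],
               domains$end[bad[1]])
  domains
}

#' Domains containing a residue position
#'
#' @param position 1-based residue index.
#' @param intervals validated domain rows for one protein.
#' @return character vector of domain names whose interval contains the
#'   position (inclusive ends), in input order; empty when none.
#' @export
map_domains <- function(position, intervals) {
  intervals <- validate_domains(intervals)
  intervals$domain_name[intervals$start <= position &
                          position <= intervals$end]
}

#' Protein-class tags for a protein
#'
#' @param protein protein identifier.
#' @param class_lists named list: tag -> character vector of protein ids
#'   (e.g. kinase, phosphatase, transcription_factor, metabolic_enzyme).
#' @return sorted character vector of tags containing the protein; empty
#'   when the protein is in no list.
#' @export
tag_protein_classes <- function(protein, class_lists) {
  if (!length(class_lists)) return(character(0))
  sort(names(class_lists)[vapply(class_lists,
                                 function(ids) protein %in% ids,
                                 logical(1))])
}

#' Read / write protein-class membership TSVs
#'
#' The on-disk format is a two-column TSV `(class, protein)`; in memory the
#' lists are a named list of protein-id vectors.
#'
#' @param class_lists named list of protein-id vectors.
#' @param path TSV path.
#' @return `read_class_lists` returns the named list; `write_class_lists`
#'   returns `path` invisibly.
#' @export
write_class_lists <- function(class_lists, path) {
  df <- bind_rows(lapply(names(class_lists), function(tag)
    tibble(class = tag, protein = class_lists[[tag]])))
  write_stage_tsv(df, path)
}

#' @rdname write_class_lists
#' @export
read_class_lists <- function(path) {
  df <- read_stage_tsv(path)
  split(df$protein, df$class)
}

#' Assemble the compendium of conserved, classified, annotated cysteines
#'
#' Inner-joins conserved cysteines with redox profiles on the mouse site
#' (oxidation data is measured on mouse tissue), then annotates each
#' surviving site with the human-side domains containing its human
#' position, the protein's class tags, and available structure ids. Sites
#' lacking oxidation data are excluded, mirroring the restriction of the
#' analysis to mapped cysteines; use `audit = TRUE` to also receive the
#' dropped sites.
#'
#' @param conserved tibble from [conserved_cysteines()] /
#'   [map_conserved_cysteines()].
#' @param profiles tibble from [redox_profiles()]; `protein` must carry the
#'   pair id and `position` the mouse position.
#' @param domains domain-interval table (human coordinates), or `NULL`.
#' @param class_lists named list of protein-id vectors, or `NULL`.
#' @param structures named list or two-column tibble
#'   (`protein`, `structure_id`), or `NULL`.
#' @param threshold classification threshold the profiles used; carried
#'   into the summary.
#' @param audit if `TRUE`, return `list(compendium, dropped)` instead.
#' @return tibble, one row per conserved cysteine with a profile, sorted by
#'   (pair_id, human_position): pair_id, mouse_position, human_position,
#'   n_conditions, delta, redox_class, domains, protein_classes,
#'   structure_ids (the latter three `;`-separated strings, possibly
#'   empty). The summary counts are attached as attribute `"summary"`.
#' @export
build_compendium <- function(conserved, profiles, domains = NULL,
                             class_lists = NULL, structures = NULL,
                             threshold = 10, audit = FALSE) {
  conserved <- as_tibble(conserved)
  profiles <- as_tibble(profiles)
  key_c <- paste(conserved$pair_id, conserved$mouse_position)
  if (anyDuplicated(key_c))
    stop_param("duplicate conserved-site key: %s",
               key_c[duplicated(key_c)][1])
  key_p <- paste(profiles$protein, profiles$position)
  if (anyDuplicated(key_p))
    stop_param("duplicate profile key: %s", key_p[duplicated(key_p)][1])
  if (!is.null(domains)) domains <- validate_domains(domains)
  if (!is.null(structures) && is.data.frame(structures))
    structures <- split(structures$structure_id, structures$protein)

  joined <- inner_join(conserved,
                       profiles %>% rename(pair_id = "protein",
                                           mouse_position = "position"),
                       by = c("pair_id", "mouse_position"))
  if (!nrow(joined))
    warning("empty compendium: no conserved cysteine has a redox profile",
            call. = FALSE)

  joined$domains <- vapply(seq_len(nrow(joined)), function(i) {
    if (is.null(domains)) return("")
    d <- domains[domains$protein == joined$pair_id[i], ]
    paste(map_domains(joined$human_position[i], d), collapse = ";")
  }, character(1))
  joined$protein_classes <- vapply(joined$pair_id, function(p)
    paste(tag_protein_classes(p, class_lists %||% list()), collapse = ";"),
    character(1), USE.NAMES = FALSE)
  joined$structure_ids <- vapply(joined$pair_id, function(p)
    paste(structures[[p]] %||% character(0), collapse = ";"), character(1),
    USE.NAMES = FALSE)

  out <- joined %>%
    select(all_of(c("pair_id", "mouse_position", "human_position",
                    "n_conditions", "delta", "redox_class", "domains",
                    "protein_classes", "structure_ids"))) %>%
    arrange(.data$pair_id, .data$human_position)
  attr(out, "summary") <- compendium_summary(out, threshold)
  if (audit) {
    dropped <- conserved[!key_c %in% paste(joined$pair_id,
                                           joined$mouse_position), ]
    return(list(compendium = out, dropped = dropped))
  }
  out
}

#' Headline counts of a compendium
#'
#' @param compendium tibble from [build_compendium()].
#' @param threshold classification threshold used (echoed in the summary).
#' @return list: n_conserved, n_dynamic, n_dynamic_with_domain, threshold.
#' @export
compendium_summary <- function(compendium, threshold = 10) {
  dyn <- compendium$redox_class == "dynamic"
  list(n_conserved = nrow(compendium),
       n_dynamic = sum(dyn),
       n_dynamic_with_domain = sum(dyn & nzchar(compendium$domains)),
       threshold = threshold)
}
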