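# Pairwise global alignment of ortholog protein sequences and projection of
# cysteine positions across species. The engine is a deterministic
# Needleman-Wunsch / Gotoh dynamic program with affine gap penalties
# (a gap of length k costs gap_open + k * gap_extend), BLOSUM62 by default.

#' Amino-acid substitution matrix by name
#'
#' Resolves a substitution matrix: either a matrix passed through unchanged
#' or a name looked up in the matrices shipped with Biostrings
#' (`"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`, ...).
#'
#' @param matrix a character name or a numeric matrix with residue dimnames.
#' @return numeric matrix with identical row and column names.
#' @export
substitution_matrix <- function(matrix = "BLOSUM62") {
  if (is.matrix(matrix)) {
    if (is.null(rownames(matrix)) || is.null(colnames(matrix)))
      stop_param("substitution matrix must have residue dimnames")
    return(matrix)
  }
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(matrix, envir = e))
    stop_param("unknown substitution matrix '%s'", matrix)
  get(matrix, envir = e)
}

validate_protein <- function(seq, name, alphabet) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop_param("`%s` must be a single non-empty protein sequence string", name)
  chars <- strsplit(seq, "")[[1]]
  bad <- which(!chars %in% alphabet)
  if (length(bad))
    stop_param("illegal residue '%s' at position %d of `%s`",
               chars[bad[1]], bad[1], name)
  invisible(chars)
}

#' Affine-gap global alignment of two protein sequences
#'
#' Computes a maximum-score global alignment under the affine gap model in
#' which a gap of length k costs `gap_open + k * gap_extend`. The traceback
#' is deterministic: where several optimal paths exist, a diagonal step is
#' preferred over a gap in `seq_b`, which is preferred over a gap in
#' `seq_a`, at every cell; the optimal score itself is unique. Terminal
#' gaps are penalised like internal gaps unless `free_end_gaps = TRUE`.
#'
#' @param seq_a,seq_b uppercase amino-acid sequence strings (`X` allowed).
#' @param substitution_matrix matrix or name, see [substitution_matrix()].
#' @param gap_open,gap_extend non-negative gap penalties (default 11 / 1).
#' @param free_end_gaps if `TRUE`, leading and trailing gaps are free.
#' @return an `alignment_result`: list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings; no column is a gap in both), `score`,
#'   and `column_count`.
#' @examples
#' aln <- global_align("MCKC", "MCKS")
#' aln$score
#' @export
global_align <- function(seq_a, seq_b, substitution_matrix = "BLOSUM62",
                         gap_open = 11, gap_extend = 1,
                         free_end_gaps = FALSE) {
  sub <- substitution_matrix(substitution_matrix)
  alphabet <- rownames(sub)
  validate_protein(seq_a, "seq_a", alphabet)
  validate_protein(seq_b, "seq_b", alphabet)
  if (gap_open < 0 || gap_extend < 0)
    stop_param("gap penalties must be non-negative")
  res <- nw_align_cpp(seq_a, seq_b, sub, paste(alphabet, collapse = ""),
                      as.numeric(gap_open), as.numeric(gap_extend),
                      isTRUE(free_end_gaps))
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, column_count = nchar(res$aligned_a)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global alignment: %d columns, score %g\n",
              x$column_count, x$score))
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  invisible(x)
}

#' Build an alignment_result from pre-aligned (gapped) sequences
#'
#' Import path for alignments produced by an external aligner (aligned
#' FASTA). No score is attached.
#'
#' @param aligned_a,aligned_b equal-length gapped sequences.
#' @return an `alignment_result` with `score = NA`.
#' @export
as_alignment <- function(aligned_a, aligned_b) {
  if (nchar(aligned_a) != nchar(aligned_b))
    stop_param("aligned sequences must have equal length")
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  if (any(ca == "-" & cb == "-"))
    stop_param("alignment has a column that is a gap in both sequences")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = NA_real_, column_count = length(ca)),
            class = "alignment_result")
}

degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Project a residue position through an alignment
#'
#' Maps 1-based residue positions in one sequence to the residue index in
#' the partner sequence occupying the same alignment column, or `NA` where
#' the partner has a gap.
#'
#' @param alignment an `alignment_result`.
#' @param position integer vector of 1-based positions in the source
#'   sequence (ungapped coordinates).
#' @param from `"a"` (default) to project a -> b, `"b"` for b -> a.
#' @return integer vector, `NA` marking gap columns.
#' @export
project_position <- function(alignment, position, from = c("a", "b")) {
  from <- match.arg(from)
  stopifnot(inherits(alignment, "alignment_result"))
  src <- strsplit(if (from == "a") alignment$aligned_a else alignment$aligned_b,
                  "")[[1]]
  dst <- strsplit(if (from == "a") alignment$aligned_b else alignment$aligned_a,
                  "")[[1]]
  src_idx <- cumsum(src != "-")
  dst_idx <- cumsum(dst != "-")
  nsrc <- src_idx[length(src_idx)]
  position <- as.integer(position)
  if (any(is.na(position)) || any(position < 1L) || any(position > nsrc))
    stop_param("position out of range 1..%d", nsrc)
  col <- match(position, src_idx * (src != "-"))
  out <- ifelse(dst[col] == "-", NA_integer_, dst_idx[col])
  as.integer(out)
}

#' Conserved cysteines of an ortholog pair
#'
#' Calls a cysteine conserved when mouse and human carry Cys in the same
#' alignment column. A cysteine aligned to a gap or to a non-Cys residue
#' yields no record.
#'
#' @param pair list with `pair_id`, `mouse`, `human` (plain sequences).
#' @param alignment optional precomputed `alignment_result` for the pair;
#'   computed with [global_align()] defaults when omitted. Must degap to
#'   the pair's sequences.
#' @param context_width residues of sequence context reported on each side
#'   of the site (default 5).
#' @param ... passed to [global_align()] when `alignment` is missing.
#' @return tibble with `pair_id`, `mouse_position`, `human_position`,
#'   `mouse_context`, `human_context`, sorted by mouse position.
#' @examples
#' conserved_cysteines(list(pair_id = "p", mouse = "MCKC", human = "MCKS"))
#' @export
conserved_cysteines <- function(pair, alignment = NULL, context_width = 5,
                                ...) {
  stopifnot(is.list(pair), !is.null(pair$mouse), !is.null(pair$human))
  pair_id <- pair$pair_id %||% "pair"
  if (is.null(alignment)) {
    alignment <- global_align(pair$mouse, pair$human, ...)
  } else {
    if (!identical(degap(alignment$aligned_a), pair$mouse) ||
        !identical(degap(alignment$aligned_b), pair$human))
      stop_param("alignment does not match the pair's sequences (pair '%s')",
                 pair_id)
  }
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  both <- which(ca == "C" & cb == "C")
  ctx <- function(seq, pos) {
    n <- nchar(seq)
    substr(seq, max(1L, pos - context_width), min(n, pos + context_width))
  }
  tibble(
    pair_id = rep(pair_id, length(both)),
    mouse_position = ia[both],
    human_position = ib[both],
    mouse_context = vapply(ia[both], function(p) ctx(pair$mouse, p),
                           character(1)),
    human_context = vapply(ib[both], function(p) ctx(pair$human, p),
                           character(1))
  ) %>% arrange(.data$mouse_position)
}

#' Map conserved cysteines across a set of ortholog pairs
#'
#' Reads two FASTA files (or `AAStringSet`s) whose record IDs pair the
#' orthologs, aligns each pair, and concatenates the per-pair conserved
#' cysteine calls. IDs present in only one file are skipped with a warning.
#'
#' @param fasta_a,fasta_b paths to FASTA files, or `Biostrings::AAStringSet`
#'   objects, for species A (mouse) and species B (human).
#' @param ... alignment parameters passed to [global_align()].
#' @return tibble as in [conserved_cysteines()], one block per shared ID.
#' @export
map_conserved_cysteines <- function(fasta_a, fasta_b, ...) {
  a <- if (inherits(fasta_a, "AAStringSet")) fasta_a else
    Biostrings::readAAStringSet(fasta_a)
  b <- if (inherits(fasta_b, "AAStringSet")) fasta_b else
    Biostrings::readAAStringSet(fasta_b)
  ids_a <- sub("\\s.*$", "", names(a))
  ids_b <- sub("\\s.*$", "", names(b))
  shared <- intersect(ids_a, ids_b)
  orphan <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(orphan))
    warning(sprintf("%d unpaired record(s) skipped: %s", length(orphan),
                    paste(head(orphan, 5), collapse = ", ")), call. = FALSE)
  out <- lapply(shared, function(id) {
    conserved_cysteines(list(pair_id = id,
                             mouse = as.character(a[[match(id, ids_a)]]),
                             human = as.character(b[[match(id, ids_b)]])),
                        ...)
  })
  bind_rows(out)
}
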