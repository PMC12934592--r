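# Shared internal helpers: argument checks, deterministic seed substreams,
# provenance-stamped TSV I/O used by every pipeline stage.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop_param("`%s` must be a single integer >= %d (got %s)",
               name, min, paste(format(x), collapse = ","))
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_param("`%s` must be a single number in [0, 1]", name)
  as.numeric(x)
}

#' Deterministic per-table seed substream
#'
#' Derives an integer seed for a named generator stream from a master seed,
#' so adding a generator call to a pipeline does not perturb the random
#' numbers consumed by earlier tables. The derivation is a fixed polynomial
#' hash of the stream name folded into the master seed, kept inside the
#' 32-bit integer range.
#'
#' @param master_seed single integer master seed.
#' @param stream character name of the stream (e.g. `"oxidation"`).
#' @return a single integer seed.
#' @export
substream_seed <- function(master_seed, stream) {
  master_seed <- check_count(master_seed, "master_seed")
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(master_seed) * 1009 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

provenance_header <- function(seed = NULL, config_hash = NULL) {
  sprintf("# redoxmap %s%s%s",
          as.character(packageVersion("redoxmap")),
          if (is.null(seed)) "" else sprintf(" seed=%d", as.integer(seed)),
          if (is.null(config_hash)) "" else sprintf(" config=%s", config_hash))
}

#' Write a pipeline table as TSV with a provenance header
#'
#' Tables are written tab-separated with a header row, preceded by a `#`
#' comment line carrying the package version, the run seed and a hash of
#' the run configuration. The header carries no timestamp so that reruns
#' with the same seed are byte-identical.
#'
#' @param x data frame to write.
#' @param path output path.
#' @param seed,config_hash optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, seed = NULL, config_hash = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(provenance_header(seed, config_hash), con)
  x <- as.data.frame(x)
  for (j in seq_along(x)) if (is.list(x[[j]]))
    x[[j]] <- vapply(x[[j]], function(v) paste(v, collapse = ";"), character(1))
  lines <- c(paste(names(x), collapse = "\t"),
             if (nrow(x)) do.call(paste, c(lapply(x, format_tsv_col), sep = "\t")))
  writeLines(lines, con)
  invisible(path)
}

format_tsv_col <- function(v) {
  if (is.numeric(v)) {
    out <- vapply(v, function(z) format(z, digits = 15, scientific = FALSE,
                                        trim = TRUE), character(1))
    out[is.na(v)] <- "NA"
    out
  } else {
    out <- as.character(v)
    out[is.na(out)] <- "NA"
    out
  }
}

#' Read a pipeline TSV written by [write_stage_tsv()]
#'
#' @param path file path.
#' @return a tibble; `#` comment lines are skipped.
#' @export
read_stage_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}
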