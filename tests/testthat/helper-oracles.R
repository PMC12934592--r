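# Independent oracles used by the tests. These deliberately share no code
# with the package: the alignment oracle enumerates every global alignment
# recursively and scores gap runs directly, rather than running a dynamic
# program.

# Best affine-gap global alignment score by exhaustive enumeration.
# state: 0 = last column was a match, 1 = gap in b (consumed a),
# 2 = gap in a (consumed b). A gap of length k costs open + k * ext.
oracle_align_score <- function(a, b, sub, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  rec <- function(i, j, state) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, sub[av[i], bv[j]] + rec(i + 1L, j + 1L, 0L))
    if (i <= n)
      best <- max(best,
                  -(ext + if (state == 1L) 0 else open) + rec(i + 1L, j, 1L))
    if (j <= m)
      best <- max(best,
                  -(ext + if (state == 2L) 0 else open) + rec(i, j + 1L, 2L))
    best
  }
  rec(1L, 1L, 0L)
}

# all sequences of the given length over an alphabet
enumerate_seqs <- function(len, alphabet) {
  if (len == 0) return(character(0))
  apply(do.call(expand.grid, rep(list(alphabet), len)), 1, paste,
        collapse = "")
}

random_protein <- function(n, alphabet = c("A", "C", "D", "E", "G", "K",
                                           "L", "P", "R", "W")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

BL62 <- substitution_matrix("BLOSUM62")
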