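# Brute-force alignment oracles.
#
# Independent of the dynamic-programming kernel: these enumerate every
# monotone alignment path (diagonal / gap-in-b / gap-in-a moves, no
# double-gap columns) and score each path directly, so they are exact for
# short sequences and serve as the reference the DP is validated against.
# Exponential in sequence length; intended for lengths <= ~6.

# Best global affine score by exhaustive path enumeration.
bruteGlobalScore <- function(a, b, scheme = defaultScoringScheme()) {
  ai <- seqToIdx(asSequence(a), scheme)
  bi <- seqToIdx(asSequence(b), scheme)
  m <- scheme@matrix
  go <- scheme@gapOpen
  ge <- scheme@gapExtend
  n <- length(ai)
  mm <- length(bi)
  best <- -Inf
  rec <- function(i, j, last, acc) {
    if (i == n && j == mm) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i < n && j < mm)
      rec(i + 1L, j + 1L, "M", acc + m[ai[i + 1L], bi[j + 1L]])
    if (i < n)
      rec(i + 1L, j, "X",
          acc - ge - if (last == "X") 0 else go)
    if (j < mm)
      rec(i, j + 1L, "Y",
          acc - ge - if (last == "Y") 0 else go)
    invisible(NULL)
  }
  rec(0L, 0L, "S", 0)
  best
}

# Best local affine score: maximum over all pairs of non-empty substrings
# of the brute-force global score, floored at 0 (empty alignment).
bruteLocalScore <- function(a, b, scheme = defaultScoringScheme()) {
  sa <- asSequence(a)
  sb <- asSequence(b)
  n <- nchar(sa)
  m <- nchar(sb)
  best <- 0
  for (i1 in seq_len(n)) for (i2 in i1:n) {
    subA <- substr(sa, i1, i2)
    for (j1 in seq_len(m)) for (j2 in j1:m) {
      s <- bruteGlobalScore(subA, substr(sb, j1, j2), scheme)
      if (s > best) best <- s
    }
  }
  best
}
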