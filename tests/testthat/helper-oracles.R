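# Independent oracles used to freeze expected values. These deliberately do
# NOT share code with the package implementation paths they check.

blosum62_oracle <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive enumeration of all global alignments of two tiny sequences
# under BLOSUM62 with affine gaps (a gap of length L costs open + L * ext).
# Returns the optimal score and the set of identical-pair counts realized
# by optimal alignments (X never counts as identical).
enumerate_global_alignment <- function(a, b, open = 10, ext = 1,
                                       mat = blosum62_oracle) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$matches <- integer()
  rec <- function(i, j, score, matches, last) {
    if (i > length(A) && j > length(B)) {
      if (score > best$score) {
        best$score <- score
        best$matches <- matches
      } else if (score == best$score) {
        best$matches <- union(best$matches, matches)
      }
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      rec(i + 1L, j + 1L, score + mat[A[i], B[j]],
          matches + as.integer(A[i] == B[j] && A[i] != "X"), "sub")
    }
    if (i <= length(A)) {
      rec(i + 1L, j, score - ext - if (last != "del") open else 0,
          matches, "del")
    }
    if (j <= length(B)) {
      rec(i, j + 1L, score - ext - if (last != "ins") open else 0,
          matches, "ins")
    }
  }
  rec(1L, 1L, 0, 0L, "sub")
  list(score = best$score, matches = best$matches)
}

# One-sided hypergeometric upper-tail probability by direct summation.
hyper_tail_oracle <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n1 <- a + b
  if (n1 == 0 || K == 0 || n1 == N || K == N) return(1)
  i <- a:min(n1, K)
  min(1, sum(exp(lchoose(K, i) + lchoose(N - K, n1 - i) - lchoose(N, n1))))
}

# Holm step-down adjustment written from the definition.
holm_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummax((m - seq_len(m) + 1) * p[o]))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Pearson correlation from the sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# Sliding-window K/R-rich interval finder written independently (naive
# per-window loop, then union of qualifying windows).
kr_oracle <- function(seq, window = 20, min_fraction = 0.4) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n < window) return(matrix(integer(), ncol = 2))
  covered <- logical(n)
  for (s in 1:(n - window + 1)) {
    w <- ch[s:(s + window - 1)]
    if (mean(w %in% c("K", "R")) >= min_fraction) {
      covered[s:(s + window - 1)] <- TRUE
    }
  }
  if (!any(covered)) return(matrix(integer(), ncol = 2))
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(starts[r$values], ends[r$values])
}
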