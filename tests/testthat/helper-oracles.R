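# Independent brute-force oracles, written without reference to the
# package internals they check.

# 2-D correlation with an odd kernel by explicit nested loops,
# replicate padding.
oracleCorrelate <- function(m, k) {
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      acc <- 0
      for (i in -kr:kr) {
        for (j in -kc:kc) {
          rr <- min(max(r + i, 1L), nr)
          cc <- min(max(c + j, 1L), nc)
          acc <- acc + k[i + kr + 1L, j + kc + 1L] * m[rr, cc]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

oracleSobelKx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
oracleSobelKy <- matrix(c(1, 2, 1, 0, 0, 0, -1, -2, -1), 3, 3, byrow = TRUE)

# Exhaustive multilevel Otsu over all increasing k-tuples of bin
# boundaries (1 .. bins-1), maximizing sum over classes of w * mu^2.
# Returns the bin-EDGE values of the lexicographically smallest argmax.
oracleOtsu <- function(counts, k) {
  bins <- length(counts)
  p <- counts / sum(counts)
  centers <- (seq_len(bins) - 0.5) / bins
  cw <- c(0, cumsum(p))
  cs <- c(0, cumsum(p * centers))
  classTerm <- function(a, b) {   # class covers bins (a, b]
    w <- cw[b + 1L] - cw[a + 1L]
    if (w <= 0) return(0)
    s <- cs[b + 1L] - cs[a + 1L]
    s * s / w
  }
  bcv <- function(cuts) {
    bounds <- c(0L, cuts, bins)
    acc <- 0
    for (i in seq_len(length(bounds) - 1L))
      acc <- acc + classTerm(bounds[i], bounds[i + 1L])
    acc
  }
  tuples <- utils::combn(bins - 1L, k)
  best <- -Inf; bt <- NULL
  for (j in seq_len(ncol(tuples))) {      # combn enumerates in lexicographic order
    v <- bcv(tuples[, j])
    if (v > best) { best <- v; bt <- tuples[, j] }
  }
  bt / bins
}

# Phantom helpers used across files.
defaultPhantom <- function(seed, ...) generatePhantom(PhantomSpec(seed = seed, ...))

diceFor <- function(seed, ...) {
  ph <- defaultPhantom(seed, ...)
  seg <- segmentHole(ph$image)
  evaluateMasks(holeMask(seg), ph$truth)$dsc
}

clamp_test <- function(x) { x[x > 1] <- 1; x[x < 0] <- 0; x }

randomMask <- function(nr, nc, p = 0.3) {
  BinaryMask(matrix(stats::rbinom(nr * nc, 1, p), nr, nc))
}
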