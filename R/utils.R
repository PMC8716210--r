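# Internal numeric helpers shared across the pipeline stages.

clamp01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

#' @noRd
mhStop <- function(class, msg, call. = FALSE) {
  cnd <- structure(
    class = c(paste0("mhseg_", class), "mhseg_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cnd)
}

# Replicate (edge-clamp) padding; pr/pc pad widths per side.
padReplicate <- function(m, pr, pc = pr) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1L, pr), seq_len(nr), rep(nr, pr))
  ci <- c(rep(1L, pc), seq_len(nc), rep(nc, pc))
  m[ri, ci, drop = FALSE]
}

padZero <- function(m, pr, pc = pr) {
  out <- matrix(0, nrow(m) + 2 * pr, ncol(m) + 2 * pc)
  out[pr + seq_len(nrow(m)), pc + seq_len(ncol(m))] <- m
  out
}

# 2-D correlation (no kernel flip) with an odd-sized kernel.
# O(kernel size) shifted-sum passes; exact, no FFT round-off.
correlate2d <- function(m, k, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  kr <- (nrow(k) - 1L) %/% 2L
  kc <- (ncol(k) - 1L) %/% 2L
  p <- if (pad == "replicate") padReplicate(m, kr, kc) else padZero(m, kr, kc)
  out <- matrix(0, nrow(m), ncol(m))
  ridx <- seq_len(nrow(m)); cidx <- seq_len(ncol(m))
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      w <- k[i, j]
      if (w != 0) out <- out + w * p[ridx + (i - 1L), cidx + (j - 1L)]
    }
  }
  out
}

# Local mean and variance over a w x w window, replicate padding.
localStats <- function(m, w) {
  box <- matrix(1 / (w * w), w, w)
  mu <- correlate2d(m, box)
  musq <- correlate2d(m * m, box)
  v <- pmax(0, musq - mu * mu)
  list(mean = mu, var = v)
}

# Separable Gaussian blur, replicate padding, kernel radius 3*sigma.
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  g <- g / sum(g)
  m <- correlate2d(m, matrix(g, ncol = 1L))   # vertical pass
  correlate2d(m, matrix(g, nrow = 1L))        # horizontal pass
}

# Moving average with replicate padding (odd window).
smoothVec <- function(x, w) {
  if (w <= 1) return(x)
  r <- (w - 1L) %/% 2L
  xp <- c(rep(x[1L], r), x, rep(x[length(x)], r))
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[r + seq_along(x)]
}

# 8-connected component labeling: EBImage::bwlabel is 4-connected, so
# diagonally touching labels are merged with a union-find pass.
label8 <- function(mask) {
  lab <- EBImage::bwlabel((mask > 0) + 0)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbor pairs (down-right and down-left shifts)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  sel <- which(a > 0L & b > 0L & a != b)
  if (length(sel)) mapply(unite, a[sel], b[sel])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  sel <- which(a > 0L & b > 0L & a != b)
  if (length(sel)) mapply(unite, a[sel], b[sel])
  roots <- vapply(seq_len(n), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

# Evaluate expr with a locally seeded RNG, restoring global state after.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stageLog <- function(verbose, stage, t0, ...) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  extra <- paste(unlist(list(...)), collapse = " ")
  message(sprintf("[mhseg] %-12s %6.2fs %s", stage,
                  as.numeric(Sys.time()) - t0, extra))
}
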