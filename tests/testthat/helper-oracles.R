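# Independent brute-force oracles used to check the package implementations.
# These deliberately share no code with the package internals.

# direct triple-sum 3x3x3 zero-padded box mean, thresholded at >= 0.5
oracleBoxSmooth <- function(v) {
  d <- dim(v)
  out <- array(0L, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    s <- 0
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      X <- x + dx; Y <- y + dy; Z <- z + dz
      if (X >= 1 && X <= d[1] && Y >= 1 && Y <= d[2] && Z >= 1 && Z <= d[3])
        s <- s + v[X, Y, Z]
    }
    out[x, y, z] <- as.integer(s / 27 >= 0.5)
  }
  out
}

# BFS flood fill of zero voxels from all faces (6-connected); tumour = complement
oracleTumorRegion <- function(v) {
  d <- dim(v)
  bg <- array(FALSE, d)
  queue <- which(v == 0L, arr.ind = TRUE)
  onFace <- queue[, 1] == 1 | queue[, 1] == d[1] |
            queue[, 2] == 1 | queue[, 2] == d[2] |
            queue[, 3] == 1 | queue[, 3] == d[3]
  frontier <- queue[onFace, , drop = FALSE]
  bg[frontier] <- TRUE
  while (nrow(frontier)) {
    nxt <- NULL
    for (k in 1:6) {
      off <- rbind(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0), c(0,0,-1), c(0,0,1))[k, ]
      cand <- sweep(frontier, 2, off, `+`)
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] & cand[, 2] >= 1 &
            cand[, 2] <= d[2] & cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      if (!nrow(cand)) next
      new <- !bg[cand] & v[cand] == 0L
      cand <- cand[new, , drop = FALSE]
      if (nrow(cand)) { bg[cand] <- TRUE; nxt <- rbind(nxt, cand) }
    }
    frontier <- if (is.null(nxt)) matrix(numeric(0), 0, 3) else unique(nxt)
  }
  out <- array(1L, d)
  out[bg] <- 0L
  out
}

# all-pairs nearest-background Euclidean distance (um), NA outside the mask
oracleDistanceMap <- function(mask, voxelSize = 10) {
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  bg <- which(mask == 0L, arr.ind = TRUE)
  fg <- which(mask == 1L, arr.ind = TRUE)
  if (!nrow(fg)) return(out)
  if (!nrow(bg)) { out[fg] <- Inf; return(out) }
  for (i in seq_len(nrow(fg))) {
    d2 <- (bg[, 1] - fg[i, 1])^2 + (bg[, 2] - fg[i, 2])^2
    out[fg[i, 1], fg[i, 2]] <- sqrt(min(d2)) * voxelSize
  }
  out
}

# forward-Euler (FTCS) diffusion with zero-flux faces and exponential decay
oracleFTCS <- function(g, D, dx, dtSec, steps, decayPerHour = 0) {
  n <- dim(g)[1]
  up <- c(2:n, n); dn <- c(1, 1:(n - 1))
  a <- D * dtSec / dx^2
  stopifnot(a <= 1 / 6)
  fac <- exp(-decayPerHour * dtSec / 3600)
  for (s in seq_len(steps)) {
    lap <- g[up, , ] + g[dn, , ] + g[, up, ] + g[, dn, ] +
           g[, , up] + g[, , dn] - 6 * g
    g <- (g + a * lap) * fac
  }
  g
}

# small immune-free parameter set (no recruitment, no necrosis)
immuneFreeParams <- function(...) {
  ruleParameters(rBase = 0, pNecrosis = 0, ...)
}
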