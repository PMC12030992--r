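# Independent brute-force oracles and tiny fixture builders shared across
# the suite. Oracles deliberately use the most naive formulation available.

# Theil-Sen by explicit double loop over all pairs.
sen_bruteforce <- function(x, years = seq_along(x)) {
  ok <- !is.na(x)
  x <- x[ok]; t <- years[ok]
  slopes <- c()
  for (i in seq_along(x)) for (j in seq_along(x)) if (j > i)
    slopes <- c(slopes, (x[j] - x[i]) / (t[j] - t[i]))
  median(slopes)
}

# q statistic by naive group-by: 1 - SSW/SST with explicit per-group sums.
q_bruteforce <- function(y, h) {
  sst <- sum((y - mean(y))^2)
  ssw <- 0
  for (g in unique(h)) {
    yg <- y[h == g]
    ssw <- ssw + sum((yg - mean(yg))^2)
  }
  1 - ssw / sst
}

# Moran's I from an explicit dense weights matrix (row-standardized rook or
# queen contiguity on a full lattice).
moran_bruteforce <- function(m, contiguity = "queen") {
  nr <- nrow(m); nc <- ncol(m)
  n <- nr * nc
  idx <- function(r, c) (c - 1) * nr + r
  W <- matrix(0, n, n)
  for (r in 1:nr) for (c in 1:nc) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      if (contiguity == "rook" && dr != 0 && dc != 0) next
      r2 <- r + dr; c2 <- c + dc
      if (r2 >= 1 && r2 <= nr && c2 >= 1 && c2 <= nc)
        W[idx(r, c), idx(r2, c2)] <- 1
    }
  }
  W <- W / rowSums(W)
  z <- as.vector(m) - mean(m)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

toy_grid <- function(values, nr = NULL) {
  if (is.null(nr)) nr <- floor(sqrt(length(values)))
  fvcdyn::grid(matrix(values, nr))
}

extdata <- function(name) {
  p <- system.file("extdata", name, package = "fvcdyn")
  if (!nzchar(p)) p <- file.path("..", "..", "inst", "extdata", name)
  read.csv(p, check.names = FALSE)
}
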