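## Independent oracles used across the suite.  All are deliberately naive /
## brute-force implementations that share no code with the package paths
## they check.

## O(n^2) causal discrete convolution.
naiveConvolve <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    j <- seq_len(min(t, length(k)))
    out[t] <- sum(k[j] * x[t - j + 1])
  }
  out
}

## Normal-equations OLS (intercept first column).
olsOracle <- function(X, y) {
  Xi <- cbind(1, X)
  as.numeric(solve(t(Xi) %*% Xi, t(Xi) %*% y))
}

## FFT-based radial high-pass of one frame, mean absolute result.
fftHighpassOracle <- function(img, cutoff = 2 * pi / 16) {
  ny <- nrow(img); nx <- ncol(img)
  FT <- stats::fft(img)
  wy <- 2 * pi * (seq_len(ny) - 1) / ny; wy <- pmin(wy, 2 * pi - wy)
  wx <- 2 * pi * (seq_len(nx) - 1) / nx; wx <- pmin(wx, 2 * pi - wx)
  keep <- outer(wy, wx, function(a, b) sqrt(a^2 + b^2)) >= cutoff
  mean(abs(Re(stats::fft(FT * keep, inverse = TRUE)) / (ny * nx)))
}

## Connected components of a 3-D mask via igraph (18-connectivity edges).
igraphComponentsOracle <- function(mask) {
  dims <- dim(mask)
  act <- which(mask)
  if (!length(act)) return(integer(0))
  id <- array(NA_integer_, dims); id[act] <- seq_along(act)
  off <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  off <- as.matrix(off[rowSums(abs(off)) %in% c(1, 2), ])
  off <- off[off[, 1] + 3 * off[, 2] + 9 * off[, 3] > 0, , drop = FALSE] # half
  ai <- arrayInd(act, dims)
  edges <- NULL
  for (o in seq_len(nrow(off))) {
    nb <- sweep(ai, 2, off[o, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    lin <- nb[ok, 1] + (nb[ok, 2] - 1) * dims[1] +
      (nb[ok, 3] - 1) * dims[1] * dims[2]
    good <- !is.na(id[lin])
    edges <- rbind(edges, cbind(id[act[ok]][good], id[lin][good]))
  }
  g <- igraph::make_empty_graph(n = length(act), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

## Multiset of component sizes from the igraph oracle.
oracleClusterSizes <- function(mask) {
  mem <- igraphComponentsOracle(mask)
  if (!length(mem)) return(integer(0))
  sort(as.integer(table(mem)))
}

## Stationary AR(1) noise, independent of the package generator.
arOracle <- function(n, sd, phi, ncol = 1) {
  m <- sapply(seq_len(ncol), function(j) {
    x <- numeric(n + 100)
    x[1] <- rnorm(1, sd = sd)
    for (t in 2:(n + 100))
      x[t] <- phi * x[t - 1] + rnorm(1, sd = sd * sqrt(1 - phi^2))
    x[101:(n + 100)]
  })
  matrix(m, n, ncol)
}

## Small synthetic study shared by several files.
tinyConfig <- function(seed = 5, ...) {
  args <- list(nSubjects = 3, nTimepoints = 80, tr = 2, nVoxels = 400,
               maskShape = c(10, 8, 5), nComponents = 4, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthConfig, args)
}
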