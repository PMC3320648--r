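## Internal helpers shared across modules.

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Stationary AR(1) series with marginal SD `sd` and coefficient `phi`.
## Innovations are scaled by sqrt(1 - phi^2) so the marginal variance is sd^2.
arNoise <- function(n, sd, phi, ncol = 1L) {
  if (sd == 0) return(matrix(0, n, ncol))
  if (phi == 0) return(matrix(rnorm(n * ncol, sd = sd), n, ncol))
  burn <- 50L
  eps <- matrix(rnorm((n + burn) * ncol, sd = sd * sqrt(1 - phi^2)),
                n + burn, ncol)
  out <- apply(eps, 2, function(e) as.numeric(stats::filter(e, phi, "recursive")))
  matrix(out[(burn + 1):(burn + n), ], n, ncol)
}

## Circular rotation of a vector: element t of the result is x[(t + s - 1) %% n + 1].
rotateVec <- function(x, s) {
  n <- length(x)
  s <- ((s %% n) + n) %% n
  if (s == 0) x else c(x[(s + 1):n], x[1:s])
}

## Circular cross-products via FFT: returns matrix D with
## D[s+1, j] = sum_t Q[t, j] * rotateVec(y, s)[t], for all shifts s = 0..n-1.
circularCrossprod <- function(Q, y) {
  n <- length(y)
  fy <- stats::fft(y)
  vapply(seq_len(ncol(Q)), function(j) {
    Re(stats::fft(Conj(stats::fft(Q[, j])) * fy, inverse = TRUE)) / n
  }, numeric(n))
}

## 100-bin lookup table of a sample: probability mass assigned to bin centers.
binTable <- function(samples, nbins = 100L) {
  rng <- range(samples)
  if (diff(rng) == 0) rng <- rng + c(-1e-12, 1e-12)
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- graphics::hist(samples, breaks = breaks, plot = FALSE)
  list(centers = h$mids, prob = h$counts / length(samples))
}

## Interpolated upper-tail threshold from a bin table: tail probability at
## each center is the mass at and above that bin (half of the center's own
## bin), linearly interpolated in between.
binThreshold <- function(centers, prob, p) {
  tail <- rev(cumsum(rev(prob))) - prob / 2
  ## tail is decreasing in centers; interpolate p -> center
  ord <- order(tail)
  stats::approx(x = tail[ord], y = centers[ord], xout = p, ties = mean,
                rule = 2)$y
}

## Pearson correlation of two vectors with an explicit zero-variance error.
safeCor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("undefined correlation: zero-variance input")
  stats::cor(a, b)
}

## Fisher z transform and inverse.
fisherZ <- function(r) atanh(r)
fisherZinv <- function(z) tanh(z)

## Greedy one-to-one matching of estimated to true signal sets by |cor|.
## Returns for each true signal the matched estimate index and the |cor|.
matchSignals <- function(truth, est) {
  ## truth: n x p matrix (columns = signals); est: n x q
  C <- abs(stats::cor(truth, est))
  p <- ncol(truth)
  match <- rep(NA_integer_, p); rho <- rep(NA_real_, p)
  Cw <- C
  for (step in seq_len(min(p, ncol(C)))) {
    idx <- which(Cw == max(Cw, na.rm = TRUE), arr.ind = TRUE)[1, ]
    match[idx[1]] <- idx[2]; rho[idx[1]] <- C[idx[1], idx[2]]
    Cw[idx[1], ] <- NA; Cw[, idx[2]] <- NA
  }
  list(index = match, rho = rho)
}

## z-score the rows of a matrix (rows with zero variance are left centered).
zscoreRows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
  s[s == 0] <- 1
  (m - mu) / s
}
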