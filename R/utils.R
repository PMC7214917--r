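# Internal numerical utilities shared across modules.

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit child seed from a master seed; stays within 32-bit range.
deriveSeed <- function(master, index, stream = 0L) {
  m <- as.double(master %% 1000003L)
  s <- (m * 8191 + as.double(index) * 7919 + as.double(stream) * 104729) %% 2147483629
  as.integer(s) + 1L
}

# Truncated, sum-normalized discrete Gaussian kernel (sigma in voxels).
gaussianKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Banded convolution matrix applying `kernel` along an axis of length n,
# zero-padded at the boundaries.
convolutionMatrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in (-r):r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  K
}

# Separable 3D Gaussian smoothing of one volume; sigmaVox per axis, voxels.
smoothVolume <- function(vol, sigmaVox) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigmaVox[ax] <= 0) next
    k <- gaussianKernel1d(sigmaVox[ax])
    if (length(k) == 1L) next
    K <- convolutionMatrix(d[ax], k)
    perm <- c(ax, setdiff(1:3, ax))
    v <- aperm(vol, perm)
    dm <- dim(v)
    v <- K %*% matrix(v, dm[1], dm[2] * dm[3])
    dim(v) <- dm
    vol <- aperm(v, order(perm))
  }
  vol
}

# Steady-state initial filter conditions for a unit-step input
# (state-space solution, direct form II transposed).
lfilterZi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  if (n == 1L) return(numeric(0))
  # companion(a) transposed
  A <- matrix(0, n - 1L, n - 1L)
  A[1L, ] <- -a[-1L]
  if (n > 2L) A[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  IminusA <- diag(n - 1L) - t(A)
  B <- b[-1L] - b[1L] * a[-1L]
  solve(IminusA, B)
}

# Apply an IIR filter along the columns of X (rows = independent series),
# direct form II transposed, vectorized across rows. zi: per-row initial
# state matrix (nrow(X) x (n-1)).
iirFilterRows <- function(b, a, X, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  V <- nrow(X); Tn <- ncol(X)
  Y <- matrix(0, V, Tn)
  Z <- vector("list", n - 1L) # state kept as plain vectors, not matrix columns
  for (k in seq_len(n - 1L))
    Z[[k]] <- if (is.null(zi)) numeric(V) else zi[, k]
  for (t in seq_len(Tn)) {
    xt <- X[, t]
    yt <- b[1] * xt + Z[[1L]]
    if (n > 2L) for (k in 1:(n - 2L))
      Z[[k]] <- b[k + 1L] * xt + Z[[k + 1L]] - a[k + 1L] * yt
    Z[[n - 1L]] <- b[n] * xt - a[n] * yt
    Y[, t] <- yt
  }
  Y
}

# Zero-phase (forward-backward) filtering of every row of X, with
# odd-reflection edge padding and steady-state initial conditions so that
# edge transients are suppressed. Equivalent in spirit to filtfilt.
filtfiltRows <- function(b, a, X, padlen = NULL) {
  n <- max(length(a), length(b))
  Tn <- ncol(X)
  if (is.null(padlen)) padlen <- 3L * n
  padlen <- as.integer(min(Tn - 1L, max(padlen, 3L * n)))
  # odd extension about the end points
  left <- 2 * X[, 1L] - X[, (padlen + 1L):2L, drop = FALSE]
  right <- 2 * X[, Tn] - X[, (Tn - 1L):(Tn - padlen), drop = FALSE]
  E <- cbind(left, X, right)
  zi <- lfilterZi(b, a)
  Y <- iirFilterRows(b, a, E, zi = outer(E[, 1L], zi))
  Y <- Y[, ncol(Y):1L, drop = FALSE]
  Y <- iirFilterRows(b, a, Y, zi = outer(Y[, 1L], zi))
  Y <- Y[, ncol(Y):1L, drop = FALSE]
  Y[, (padlen + 1L):(padlen + Tn), drop = FALSE]
}

# 26-neighbourhood offsets (or 6) for 3D connected components.
neighbourOffsets <- function(connectivity = 26L) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  if (connectivity == 6L) g <- g[abs(g$dx) + abs(g$dy) + abs(g$dz) == 1L, ]
  as.matrix(g)
}

#' Label connected components of a 3D binary mask
#'
#' Flood-fill labeling under 6- or 26-connectivity, used by the lesion
#' delineation cluster-size filter.
#'
#' @param mask logical 3D array.
#' @param connectivity 6 or 26.
#' @return Integer array of the same shape; 0 = background, components
#'   numbered from 1 in scan order.
#' @examples
#' m <- array(FALSE, c(4, 4, 1))
#' m[1:2, 1:2, 1] <- TRUE; m[4, 4, 1] <- TRUE
#' table(labelComponents(m))
#' @export
labelComponents <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  stopifnot(length(d) == 3L, connectivity %in% c(6L, 26L))
  off <- neighbourOffsets(as.integer(connectivity))
  lab <- array(0L, d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  comp <- 0L
  for (seed in idx) {
    if (lab[seed] != 0L) next
    comp <- comp + 1L
    frontier <- seed
    lab[seed] <- comp
    while (length(frontier)) {
      co <- arrayInd(frontier, d)
      nb <- integer(0)
      for (k in seq_len(nrow(off))) {
        cx <- co[, 1L] + off[k, 1L]
        cy <- co[, 2L] + off[k, 2L]
        cz <- co[, 3L] + off[k, 3L]
        ok <- cx >= 1L & cx <= d[1L] & cy >= 1L & cy <= d[2L] & cz >= 1L & cz <= d[3L]
        if (!any(ok)) next
        lin <- cx[ok] + (cy[ok] - 1L) * d[1L] + (cz[ok] - 1L) * d[1L] * d[2L]
        nb <- c(nb, lin[mask[lin] & lab[lin] == 0L])
      }
      nb <- unique(nb)
      lab[nb] <- comp
      frontier <- nb
    }
  }
  lab
}

# Small stable string hash (djb2) for config fingerprints; no external deps.
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 4294967291
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Row-wise cumulative sums along columns, preallocated (V x T).
rowCumsums <- function(X) {
  C <- X
  for (t in 2:ncol(X)) C[, t] <- C[, t - 1L] + X[, t]
  C
}
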