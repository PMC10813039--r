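# Independent brute-force oracles used across the suite. These deliberately
# use naive loops / closed forms, never the package's own vectorized code.

# naive per-pixel double loop for the vitreous haze ratio
naive_vh <- function(intensities, ilm) {
  vit <- c(); below <- c()
  for (b in seq_len(dim(intensities)[1])) {
    for (a in seq_len(dim(intensities)[2])) {
      d0 <- ilm[b, a]
      if (is.na(d0)) next
      for (d in seq_len(dim(intensities)[3])) {
        if (d < d0) vit <- c(vit, intensities[b, a, d])
        else below <- c(below, intensities[b, a, d])
      }
    }
  }
  mean(vit) / mean(below)
}

# per-pixel mask oracle for ETDRS sector means
mask_sector_means <- function(map) {
  th <- map$thickness_um
  nb <- nrow(th); na_ <- ncol(th)
  out <- list()
  for (s in c("inner_superior", "inner_inferior", "inner_nasal",
              "inner_temporal", "outer_superior", "outer_inferior",
              "outer_nasal", "outer_temporal")) out[[s]] <- c()
  for (i in seq_len(nb)) {
    for (j in seq_len(na_)) {
      dy <- (i - map$fovea_center[1]) * map$bscan_spacing_um / 1000
      dx <- (j - map$fovea_center[2]) * map$ascan_spacing_um / 1000
      if (map$eye == "OS") dx <- -dx
      r <- sqrt(dx^2 + dy^2)
      if (r <= 0.5 || r > 1.7) next
      ring <- if (r <= 1.11) "inner" else "outer"
      u <- -dy
      quad <- if (dx >= u && dx > -u) "nasal"
        else if (u > dx && u >= -dx) "superior"
        else if (-dx > u && u >= dx) "temporal"
        else "inferior"
      key <- paste(ring, quad, sep = "_")
      out[[key]] <- c(out[[key]], th[i, j])
    }
  }
  vapply(out, mean, numeric(1))
}

# O(n^2) pairwise-comparison count for the Mann-Whitney U statistic
naive_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# textbook sandwich covariance, naive per-cluster solve()
textbook_sandwich <- function(X, y, id, beta, rho, phi) {
  p <- ncol(X)
  A <- matrix(0, p, p); M <- matrix(0, p, p)
  for (g in unique(id)) {
    idx <- which(id == g)
    Xi <- X[idx, , drop = FALSE]
    ri <- y[idx] - Xi %*% beta
    ni <- length(idx)
    Vi <- phi * ((1 - rho) * diag(ni) + rho * matrix(1, ni, ni))
    Vinv <- solve(Vi)
    A <- A + t(Xi) %*% Vinv %*% Xi
    M <- M + t(Xi) %*% Vinv %*% ri %*% t(ri) %*% Vinv %*% Xi
  }
  Ainv <- solve(A)
  Ainv %*% M %*% Ainv
}

# closed-form GLS with compound-symmetry covariance, naive per-cluster
oracle_gls <- function(X, y, id, rho, phi = 1) {
  p <- ncol(X)
  A <- matrix(0, p, p); b <- matrix(0, p, 1)
  for (g in unique(id)) {
    idx <- which(id == g)
    Xi <- X[idx, , drop = FALSE]
    ni <- length(idx)
    Vi <- phi * ((1 - rho) * diag(ni) + rho * matrix(1, ni, ni))
    Vinv <- solve(Vi)
    A <- A + t(Xi) %*% Vinv %*% Xi
    b <- b + t(Xi) %*% Vinv %*% y[idx]
  }
  drop(solve(A, b))
}

# brute-force NA-aware 2-D median filter (R reference for the C++ kernel)
naive_median_filter <- function(m, window) {
  half <- (window - 1) / 2
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (is.na(m[i, j])) { out[i, j] <- NA; next }
      ri <- max(1, i - half):min(nrow(m), i + half)
      rj <- max(1, j - half):min(ncol(m), j + half)
      v <- m[ri, rj]
      # ties round half away from zero, like the compiled kernel
      out[i, j] <- as.integer(floor(stats::median(v[!is.na(v)]) + 0.5))
    }
  }
  out
}

# small raw volume with a flat ILM step at depth d (vitreous value v0,
# retina value v1)
step_volume <- function(nb = 2, na_ = 3, nd = 16, d = 6, v0 = 0, v1 = 1) {
  arr <- array(v0, c(nb, na_, nd))
  arr[, , d:nd] <- v1
  raw_oct_volume(arr, 3.9, 11.7)
}
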