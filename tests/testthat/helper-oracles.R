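# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own implementation paths: plain loops, naive sums.

rand_gray <- function(nr, nc, max_value = 255, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gray_image(matrix(sample(0:max_value, nr * nc, replace = TRUE), nr, nc),
             max_value)
}

# median filter oracle: per-pixel sort-and-pick-middle with replicated edges
oracle_median3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- numeric(9); t <- 0
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      t <- t + 1; vals[t] <- m[ii, jj]
    }
    out[i, j] <- sort(vals)[5]
  }
  out
}

# classical Otsu oracle: exhaustive search maximising between-class variance
oracle_otsu <- function(g, max_value = 255) {
  best_t <- NA; best_v <- -Inf
  n <- length(g)
  for (t in 0:(max_value - 1)) {
    lo <- g[g <= t]; hi <- g[g > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n; w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# GLCM oracle: double loop over pixels
oracle_glcm <- function(lev, Ng, direction, symmetric) {
  off <- list(`0` = c(0, 1), `45` = c(-1, 1), `90` = c(-1, 0),
              `135` = c(-1, -1))[[as.character(direction)]]
  P <- matrix(0, Ng, Ng)
  nr <- nrow(lev); nc <- ncol(lev)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[1]; jj <- j + off[2]
    if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
      P[lev[i, j], lev[ii, jj]] <- P[lev[i, j], lev[ii, jj]] + 1
      if (symmetric) P[lev[ii, jj], lev[i, j]] <- P[lev[ii, jj], lev[i, j]] + 1
    }
  }
  P / sum(P)
}

# GLRLM oracle: explicit line walking per direction
oracle_glrlm <- function(lev, Ng, direction) {
  nr <- nrow(lev); nc <- ncol(lev)
  step <- list(`0` = c(0, 1), `90` = c(1, 0), `45` = c(-1, 1),
               `135` = c(-1, -1))[[as.character(direction)]]
  starts <- switch(as.character(direction),
    `0`   = cbind(seq_len(nr), 1),
    `90`  = cbind(1, seq_len(nc)),
    `45`  = rbind(cbind(seq_len(nr), 1), cbind(nr, 1 + seq_len(nc - 1))),
    `135` = rbind(cbind(seq_len(nr), nc), cbind(nr, seq_len(nc - 1))))
  Lmax <- switch(as.character(direction), `0` = nc, `90` = nr,
                 min(nr, nc))
  R <- matrix(0, Ng, Lmax)
  for (s in seq_len(nrow(starts))) {
    i <- starts[s, 1]; j <- starts[s, 2]
    run_val <- NA; run_len <- 0
    while (i >= 1 && i <= nr && j >= 1 && j <= nc) {
      v <- lev[i, j]
      if (!is.na(run_val) && v == run_val) {
        run_len <- run_len + 1
      } else {
        if (run_len > 0) R[run_val, run_len] <- R[run_val, run_len] + 1
        run_val <- v; run_len <- 1
      }
      i <- i + step[1]; j <- j + step[2]
    }
    if (run_len > 0) R[run_val, run_len] <- R[run_val, run_len] + 1
  }
  R
}

# naive GLCM descriptor evaluation by explicit double sums
oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  energy <- 0; contrast <- 0; entropy <- 0; homog <- 0; shade <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    mu_i <- mu_i + i * P[i, j]; mu_j <- mu_j + j * P[i, j]
  }
  sd_i <- 0; sd_j <- 0; corr_num <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + (i - j)^2 * p
    if (p > 0) entropy <- entropy - p * log2(p)
    homog <- homog + p / (1 + abs(i - j))
    shade <- shade + (i + j - mu_i - mu_j)^3 * p
    sd_i <- sd_i + (i - mu_i)^2 * p
    sd_j <- sd_j + (j - mu_j)^2 * p
    corr_num <- corr_num + (i - mu_i) * (j - mu_j) * p
  }
  corr <- if (sd_i == 0 || sd_j == 0) 0 else corr_num / sqrt(sd_i * sd_j)
  c(energy = energy, contrast = contrast, entropy = entropy,
    homogeneity = homog, correlation = corr, shade = shade)
}

oracle_glrlm_features <- function(R, Nr) {
  sre <- 0; lre <- 0; lgre <- 0; hgre <- 0; gln <- 0
  for (i in seq_len(nrow(R))) {
    rs <- 0
    for (j in seq_len(ncol(R))) {
      sre <- sre + R[i, j] / j^2
      lre <- lre + R[i, j] * j^2
      lgre <- lgre + R[i, j] / i^2
      hgre <- hgre + R[i, j] * i^2
      rs <- rs + R[i, j]
    }
    gln <- gln + rs^2
  }
  c(sre = sre, lre = lre, lgre = lgre, hgre = hgre, gln = gln) / Nr
}
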