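# Independent brute-force oracles. These re-derive each operation from its
# definition with naive per-pixel loops, deliberately sharing no code with
# the implementation under test.

randMask <- function(h = 16L, w = 16L, p = 0.4) {
  matrix(as.integer(runif(h * w) < p), h, w)
}

# naive 3x3 neighbourhood-scan dilation/erosion, outside-frame = background
oracleDilate1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- 0L
    for (di in -1:1) for (dj in -1:1) {
      r <- i + di; c <- j + dj
      if (r >= 1 && r <= H && c >= 1 && c <= W && m[r, c] == 1L) v <- 1L
    }
    out[i, j] <- v
  }
  out
}

oracleErode1 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0L, H, W)
  for (i in 1:H) for (j in 1:W) {
    v <- 1L
    for (di in -1:1) for (dj in -1:1) {
      r <- i + di; c <- j + dj
      if (r < 1 || r > H || c < 1 || c > W || m[r, c] == 0L) v <- 0L
    }
    out[i, j] <- v
  }
  out
}

oracleMorph <- function(m, op, iterations) {
  for (k in seq_len(iterations)) m <- op(m)
  m
}

# exhaustive Otsu: try all 256 thresholds, maximize between-class variance
# computed directly from the pixel partition; lowest maximizer wins
oracleOtsu <- function(px) {
  v <- as.vector(px)
  best <- -Inf; bt <- NA_integer_
  for (t in 0:255) {
    g0 <- v[v <= t]; g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(v)
    s <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (s > best) { best <- s; bt <- t }
  }
  bt
}

# naive windowed statistics with edge replication (index clamping)
oracleWindowStats <- function(px, r) {
  H <- nrow(px); W <- ncol(px)
  out <- list(mean = matrix(0, H, W), median = matrix(0, H, W),
              variance = matrix(0, H, W), entropy = matrix(0, H, W))
  for (i in 1:H) for (j in 1:W) {
    vals <- integer(0)
    for (di in -r:r) for (dj in -r:r) {
      rr <- min(max(i + di, 1), H)
      cc <- min(max(j + dj, 1), W)
      vals <- c(vals, px[rr, cc])
    }
    n <- length(vals)
    m <- mean(vals)
    out$mean[i, j] <- m
    out$median[i, j] <- sort(vals)[(n + 1) %/% 2]
    out$variance[i, j] <- mean((vals - m)^2)
    p <- table(vals) / n
    out$entropy[i, j] <- -sum(p * log2(p))
  }
  out
}

# 8-connected component count by BFS (independent of cpp_label)
oracleComponents8 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  count <- 0L
  for (i in 1:H) for (j in 1:W) {
    if (m[i, j] == 0L || seen[i, j]) next
    count <- count + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            m[r, c] == 1L && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  count
}

diceCoef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
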