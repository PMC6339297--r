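# Independent brute-force oracles used to pin down the arithmetic of the
# fast implementations. These stay deliberately naive: per-pixel loops,
# exhaustive scans, recursion.

# Valid multi-channel convolution, one output pixel at a time.
oracle_conv2d <- function(X, W) {
  M <- dim(X)[1]; K <- dim(W)[2]
  ho <- dim(X)[2] - K + 1; wo <- dim(X)[3] - K + 1
  Y <- matrix(0, ho, wo)
  for (i in 1:ho) for (j in 1:wo) {
    acc <- 0
    for (m in 1:M) for (k in 1:K) for (l in 1:K) {
      acc <- acc + W[m, k, l] * X[m, k + i - 1, l + j - 1]
    }
    Y[i, j] <- acc
  }
  Y
}

# Gaussian candidate scoring with zero padding, double loop per pixel.
oracle_score_map <- function(V, W) {
  H <- nrow(V); Wd <- ncol(V)
  hk <- (nrow(W) - 1) / 2
  S <- matrix(0, H, Wd)
  for (i in 1:H) for (j in 1:Wd) {
    acc <- 0
    for (a in -hk:hk) for (b in -hk:hk) {
      ii <- i + a; jj <- j + b
      if (ii >= 1 && ii <= H && jj >= 1 && jj <= Wd) {
        acc <- acc + W[a + hk + 1, b + hk + 1] * V[ii, jj]
      }
    }
    S[i, j] <- acc
  }
  S
}

# Max pooling window by window.
oracle_max_pool <- function(X, L, stride) {
  ys <- seq(1, nrow(X), by = stride)
  xs <- seq(1, ncol(X), by = stride)
  out <- matrix(0, length(ys), length(xs))
  for (a in seq_along(ys)) for (b in seq_along(xs)) {
    out[a, b] <- max(X[ys[a]:min(ys[a] + L - 1, nrow(X)),
                       xs[b]:min(xs[b] + L - 1, ncol(X))])
  }
  out
}

# Exhaustive-threshold Otsu: maximize between-class variance over all
# midpoints between consecutive distinct values; foreground = img > t.
oracle_otsu_mask <- function(img) {
  v <- sort(unique(as.vector(img)))
  if (length(v) < 2) return(matrix(0, nrow(img), ncol(img)))
  cuts <- (v[-1] + v[-length(v)]) / 2
  n <- length(img)
  best <- -Inf; best_cut <- cuts[1]
  for (t in cuts) {
    fg <- img > t
    w1 <- sum(fg) / n
    if (w1 == 0 || w1 == 1) next
    bc <- w1 * (1 - w1) * (mean(img[fg]) - mean(img[!fg]))^2
    if (bc > best) { best <- bc; best_cut <- t }
  }
  (img > best_cut) * 1
}

# Per-cell exhaustive argmax with row-major tie-breaking.
oracle_cell_argmax <- function(S, g) {
  H <- nrow(S); W <- ncol(S)
  out <- NULL
  for (cy in seq_len(ceiling(H / g))) for (cx in seq_len(ceiling(W / g))) {
    rows <- ((cy - 1) * g + 1):min(cy * g, H)
    cols <- ((cx - 1) * g + 1):min(cx * g, W)
    best <- -Inf; by <- NA; bx <- NA
    for (r in rows) for (c in cols) {
      if (S[r, c] > best) { best <- S[r, c]; by <- r; bx <- c }
    }
    out <- rbind(out, c(x = bx - 1, y = by - 1, score = best))
  }
  as.data.frame(out)
}

# Reference NMS: repeatedly take the best remaining candidate and discard
# everything closer than min_sep to it.
oracle_nms <- function(df, min_sep) {
  df <- df[order(-df$score, df$y, df$x), , drop = FALSE]
  kept <- df[0, ]
  while (nrow(df) > 0) {
    top <- df[1, , drop = FALSE]
    kept <- rbind(kept, top)
    d2 <- (df$x - top$x)^2 + (df$y - top$y)^2
    df <- df[d2 >= min_sep^2, , drop = FALSE]
  }
  kept
}

# Maximum bipartite matching size (optimal TP) by recursion; feasible edges
# are pick/truth pairs within the distance threshold.
oracle_max_matching <- function(pred, truth, thr) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(0)
  adj <- outer(seq_len(np), seq_len(nt), function(i, j) {
    sqrt((pred$x[i] - truth$x[j])^2 + (pred$y[i] - truth$y[j])^2) <= thr
  })
  rec <- function(i, used) {
    if (i > np) return(0)
    best <- rec(i + 1, used)                 # leave pick i unmatched
    for (j in which(adj[i, ] & !used)) {
      used[j] <- TRUE
      best <- max(best, 1 + rec(i + 1, used))
      used[j] <- FALSE
    }
    best
  }
  rec(1, rep(FALSE, nt))
}

# Analytic disc mask of radius r centered at 0-based (cx, cy).
oracle_disc_mask <- function(H, W, cx, cy, r) {
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), times = W), H, W)
  ((xs - cx)^2 + (ys - cy)^2 <= r^2) * 1
}

# Small simulation shared across tests: fast but non-trivial.
tiny_sim <- function(seed = 11, n = 5, mic = 192) {
  simulate_micrograph(sim_config(mic_shape = c(mic, mic), n_particles = n,
                                 seed = seed))
}
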