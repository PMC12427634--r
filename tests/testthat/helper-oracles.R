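# Independent brute-force oracles, deliberately written in the most direct
# (slow) way so they share no code path with the implementation.

oracle_median_filter <- function(img, window) {
  h <- nrow(img); w <- ncol(img); r <- window %/% 2
  out <- img
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      vals <- c()
      for (dy in -r:r) {
        for (dx in -r:r) {
          yy <- min(max(y + dy, 1), h)
          xx <- min(max(x + dx, 1), w)
          vals <- c(vals, img[yy, xx])
        }
      }
      out[y, x] <- sort(vals)[(length(vals) + 1) %/% 2]
    }
  }
  out
}

oracle_otsu <- function(img) {
  v <- as.vector(img)
  n <- length(v)
  best_t <- NA; best_s <- -Inf
  for (t in 0:255) {
    c0 <- v[v <= t]; c1 <- v[v > t]
    if (length(c0) == 0 || length(c1) == 0) next
    w0 <- length(c0) / n; w1 <- length(c1) / n
    s <- w0 * w1 * (mean(c0) - mean(c1))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

oracle_adaptive <- function(img, block, offset) {
  h <- nrow(img); w <- ncol(img); r <- block %/% 2
  out <- img
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      vals <- c()
      for (dy in -r:r) {
        for (dx in -r:r) {
          vals <- c(vals, img[min(max(y + dy, 1), h), min(max(x + dx, 1), w)])
        }
      }
      out[y, x] <- if (img[y, x] > mean(vals) - offset) 255L else 0L
    }
  }
  out
}

# flood-fill component labeling, 8-connected; returns list of pixel-index sets
oracle_components <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  seen <- matrix(FALSE, h, w)
  comps <- list()
  for (y0 in seq_len(h)) {
    for (x0 in seq_len(w)) {
      if (bin[y0, x0] == 0 || seen[y0, x0]) next
      stack <- list(c(y0, x0)); seen[y0, x0] <- TRUE
      px <- c()
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        px <- c(px, (p[1] - 1) + (p[2] - 1) * h)
        for (dy in -1:1) {
          for (dx in -1:1) {
            yy <- p[1] + dy; xx <- p[2] + dx
            if (yy >= 1 && yy <= h && xx >= 1 && xx <= w &&
              bin[yy, xx] != 0 && !seen[yy, xx]) {
              seen[yy, xx] <- TRUE
              stack[[length(stack) + 1]] <- c(yy, xx)
            }
          }
        }
      }
      comps[[length(comps) + 1]] <- sort(px)
    }
  }
  comps
}

oracle_largest_component_mask <- function(bin) {
  comps <- oracle_components(bin)
  areas <- vapply(comps, length, integer(1))
  best <- which(areas == max(areas))
  if (length(best) > 1) {
    # row-major first pixel: convert column-major index to (x, y)
    h <- nrow(bin)
    key <- vapply(best, function(i) {
      idx <- comps[[i]]
      y <- idx %% h; x <- idx %/% h
      min(y * ncol(bin) + x)
    }, numeric(1))
    best <- best[which.min(key)]
  }
  out <- matrix(0L, nrow(bin), ncol(bin))
  out[comps[[best]] + 1] <- 255L
  out
}

oracle_extrema <- function(mask) {
  h <- nrow(mask)
  idx <- which(mask == 255L)
  x <- (idx - 1) %/% h; y <- (idx - 1) %% h
  sel <- function(f) {
    m <- max(f)
    cand <- which(f == m)
    cand <- cand[order(y[cand], x[cand])]
    c(x = x[cand[1]], y = y[cand[1]])
  }
  list(
    bottom_left = sel(y - x), bottom_right = sel(y + x),
    top_left = sel(-(y + x)), top_right = sel(-(y - x))
  )
}

# PR staircase integration by explicit rectangle sum with right-side
# precision envelope computed per point by a max() scan
oracle_ap <- function(confidence, is_tp, n_truth) {
  ord <- order(confidence, decreasing = TRUE)
  is_tp <- is_tp[ord]
  rec <- prec <- numeric(length(is_tp))
  tp <- 0
  for (i in seq_along(is_tp)) {
    tp <- tp + as.integer(is_tp[i])
    rec[i] <- tp / n_truth
    prec[i] <- tp / i
  }
  ap <- 0; prev_r <- 0
  for (i in seq_along(rec)) {
    p_env <- max(prec[i:length(prec)])
    ap <- ap + (rec[i] - prev_r) * p_env
    prev_r <- rec[i]
  }
  ap
}

oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  cov <- sum((x - mx) * (y - my)) / (length(x) - 1)
  sx <- sqrt(sum((x - mx)^2) / (length(x) - 1))
  sy <- sqrt(sum((y - my)^2) / (length(y) - 1))
  cov / (sx * sy)
}

oracle_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  u <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (u <= 0) 0 else inter / u
}

# greedy per-class matching, plain loops over data frames
oracle_match <- function(pred, truth, thr) {
  labs <- sort(unique(c(pred$label, truth$label)))
  res <- NULL
  for (lab in labs) {
    p <- pred[pred$label == lab, , drop = FALSE]
    tr <- truth[truth$label == lab, , drop = FALSE]
    p <- p[order(-p$confidence), , drop = FALSE]
    used <- rep(FALSE, nrow(tr))
    tp <- 0; fp <- 0
    for (i in seq_len(nrow(p))) {
      best_j <- 0; best_iou <- -1
      for (j in seq_len(nrow(tr))) {
        if (used[j]) next
        iou <- oracle_iou(
          c(p$x_min[i], p$y_min[i], p$x_max[i], p$y_max[i]),
          c(tr$x_min[j], tr$y_min[j], tr$x_max[j], tr$y_max[j])
        )
        if (iou > best_iou) { best_iou <- iou; best_j <- j }
      }
      if (best_j > 0 && best_iou >= thr) { used[best_j] <- TRUE; tp <- tp + 1 } else fp <- fp + 1
    }
    res <- rbind(res, data.frame(label = lab, tp = tp, fp = fp, fn = sum(!used), tn = 0L))
  }
  res
}

rand_gray <- function(h, w, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(sample(0:255, h * w, replace = TRUE)), h, w)
}

rand_binary <- function(h, w, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(ifelse(stats::runif(h * w) < p, 255L, 0L), h, w)
}
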