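# Shared fixtures, memoised so expensive objects are built once per session.

.fixtures <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixtures, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

default_bundle <- function(seed = 1L) {
  cached_fixture(paste0("bundle_", seed), generate_paired_dataset(seed = seed))
}

bundle_features <- function(seed = 1L) {
  cached_fixture(paste0("features_", seed), {
    suppressWarnings(extract_features_batch(default_bundle(seed)))
  })
}

dice_overlap <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

flat_rgb <- function(H, W, color) {
  arr <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) arr[, , ch] <- color[ch]
  arr
}

paint_mask <- function(rgb, mask, color) {
  for (ch in 1:3) {
    plane <- rgb[, , ch]
    plane[mask] <- color[ch]
    rgb[, , ch] <- plane
  }
  rgb
}

disk_mask <- function(H, W, cx, cy, r) {
  outer(seq_len(H), seq_len(W), function(i, j) (i - cy)^2 + (j - cx)^2 <= r^2)
}

# Radially shaded blob in the style of the synthetic nuclei: darker core,
# brighter rim, constant hue.
paint_shaded_disk <- function(rgb, cx, cy, r, color, core = 0.85, rim = 1.30) {
  H <- dim(rgb)[1]
  W <- dim(rgb)[2]
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      d <- sqrt((i - cy)^2 + (j - cx)^2)
      if (d <= r) {
        f <- core + (rim - core) * (d / r)^1.5
        rgb[i, j, ] <- pmin(color * f, 255)
      }
    }
  }
  rgb
}

sierpinski_carpet <- function(depth) {
  m <- matrix(TRUE, 1, 1)
  for (i in seq_len(depth)) {
    z <- matrix(FALSE, nrow(m), ncol(m))
    m <- rbind(cbind(m, m, m), cbind(m, z, m), cbind(m, m, m))
  }
  m
}

# Independent brute-force mRMR oracle: evaluates the greedy criterion for
# every candidate at every step with table()-based mutual information.
oracle_mi <- function(x, y) {
  disc <- function(v) {
    if (length(unique(v)) <= min(10, ceiling(sqrt(length(v))))) {
      return(as.integer(as.factor(v)))
    }
    edges <- unique(quantile(v, seq(0, 1, length.out = min(10, ceiling(sqrt(length(v)))) + 1),
                             names = FALSE))
    findInterval(v, edges, rightmost.closed = TRUE, all.inside = TRUE)
  }
  tab <- table(disc(x), disc(y))
  pj <- tab / sum(tab)
  px <- rowSums(pj)
  py <- colSums(pj)
  total <- 0
  for (i in seq_along(px)) {
    for (j in seq_along(py)) {
      if (pj[i, j] > 0) {
        total <- total + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
      }
    }
  }
  max(total, 0)
}

oracle_mrmr <- function(X, y, m) {
  p <- ncol(X)
  rel <- vapply(seq_len(p), function(j) oracle_mi(X[[j]], y), numeric(1))
  selected <- integer(0)
  for (step in seq_len(m)) {
    remaining <- setdiff(seq_len(p), selected)
    scores <- vapply(remaining, function(j) {
      red <- if (length(selected) == 0) 0 else {
        mean(vapply(selected, function(s) oracle_mi(X[[j]], X[[s]]), numeric(1)))
      }
      rel[j] - red
    }, numeric(1))
    selected <- c(selected, remaining[which.max(scores)])
  }
  selected
}
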