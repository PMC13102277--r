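# Independent brute-force reference implementations used as oracles.

# O(n^2) DBSCAN by direct range queries; returns labels (0 = noise).
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cid <- cid + 1L
    queue <- i
    labels[i] <- cid
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (!core[j]) next
      for (q in nb[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cid
          queue <- c(queue, q)
        }
      }
    }
  }
  labels
}

# partition of indices by label, as a canonical sorted list of sorted sets
partition_sets <- function(labels) {
  s <- split(seq_along(labels)[labels > 0], labels[labels > 0])
  unname(s[order(vapply(s, min, integer(1)))])
}

# O(n^2) nearest-neighbour distances
brute_nn <- function(ax, ay, bx, by, self = FALSE) {
  vapply(seq_along(ax), function(i) {
    d <- sqrt((bx - ax[i])^2 + (by - ay[i])^2)
    if (self) d[i] <- Inf
    min(d)
  }, numeric(1))
}

# connected components of the linking pair graph, by repeated BFS
brute_link_components <- function(x, y, frame, radius, max_dark) {
  n <- length(x)
  adj <- lapply(seq_len(n), function(i) {
    df <- abs(frame - frame[i])
    which(df >= 1 & df <= max_dark + 1 &
            (x - x[i])^2 + (y - y[i])^2 <= radius^2)
  })
  comp <- integer(n); cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cid <- cid + 1L
    queue <- i; comp[i] <- cid
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      for (q in adj[[j]]) if (comp[q] == 0L) { comp[q] <- cid; queue <- c(queue, q) }
    }
  }
  comp
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
enum_mw_p <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_stat <- function(ia) {
    xa <- pooled[ia]; xb <- pooled[-ia]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  obs <- u_stat(seq_len(na))
  combs <- utils::combn(length(pooled), na, simplify = FALSE)
  us <- vapply(combs, u_stat, numeric(1))
  mu <- na * length(b) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# fan triangulation area for a polygon star-shaped around c0
triangulation_area <- function(poly, c0 = colMeans(poly)) {
  n <- nrow(poly)
  sum(vapply(seq_len(n), function(i) {
    j <- if (i == n) 1L else i + 1L
    abs((poly[i, 1] - c0[1]) * (poly[j, 2] - c0[2]) -
          (poly[j, 1] - c0[1]) * (poly[i, 2] - c0[2])) / 2
  }, numeric(1)))
}

# random star-shaped simple polygon around a center
random_star_polygon <- function(n = 12, r_mean = 2000, center = c(3000, 3000)) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, 0.4 * r_mean, 1.6 * r_mean)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}
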