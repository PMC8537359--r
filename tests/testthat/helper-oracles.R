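# Independent brute-force oracles. These deliberately use naive
# enumeration (per-seed BFS maps, double loops, exhaustive threshold
# search) so they share no code path with the package implementation.

# Nearest-seed partition by per-seed geodesic BFS (4-connected), ties to
# the smaller label. Seed pixels always keep their own label.
oracle_nearest_seed <- function(seeds, foreground) {
  nr <- nrow(seeds); nc <- ncol(seeds)
  labs <- sort(unique(seeds[seeds > 0]))
  dmaps <- lapply(labs, function(l) oracle_geodesic_dist(seeds == l, foreground))
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (seeds[i, j] > 0) { out[i, j] <- seeds[i, j]; next }
    if (!foreground[i, j]) next
    dd <- vapply(dmaps, function(d) d[i, j], numeric(1))
    if (all(!is.finite(dd))) next
    out[i, j] <- labs[which(dd == min(dd))[1]]   # labs sorted: min label
  }
  out
}

# Geodesic distance (in steps through foreground) from a source region.
oracle_geodesic_dist <- function(source, foreground) {
  nr <- nrow(source); nc <- ncol(source)
  d <- matrix(Inf, nr, nc)
  frontier <- which(source & foreground)
  d[frontier] <- 0
  step <- 0
  while (length(frontier)) {
    step <- step + 1
    nxt <- integer(0)
    for (idx in frontier) {
      i <- (idx - 1) %% nr + 1; j <- (idx - 1) %/% nr + 1
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ni <- i + o[1]; nj <- j + o[2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (!foreground[ni, nj]) next
        k <- (nj - 1) * nr + ni
        if (d[k] > step) { d[k] <- step; nxt <- c(nxt, k) }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

# Exhaustive between-class-variance maximiser over all integer cut
# levels; returns the cut level k such that foreground is "value > k".
oracle_otsu <- function(gray, levels = 256) {
  cnt <- tabulate(as.integer(gray) + 1L, levels)
  lev <- 0:(levels - 1)
  n <- sum(cnt)
  best <- -Inf; cut <- NA_integer_
  for (k in seq_len(levels - 1)) {
    w0 <- sum(cnt[1:k]); w1 <- n - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(cnt[1:k] * lev[1:k]) / w0
    m1 <- sum(cnt[(k + 1):levels] * lev[(k + 1):levels]) / w1
    v <- w0 * w1 * (m0 - m1)^2
    if (v > best) { best <- v; cut <- lev[k] }
  }
  cut
}

# Naive per-label accumulation loop.
oracle_measure <- function(labels, intensity) {
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs))
    return(data.frame(cell_id = integer(0), area = numeric(0),
                      mean_intensity = numeric(0)))
  do.call(rbind, lapply(labs, function(l) {
    s <- 0; n <- 0
    for (i in seq_len(nrow(labels))) for (j in seq_len(ncol(labels)))
      if (labels[i, j] == l) { s <- s + intensity[i, j]; n <- n + 1 }
    data.frame(cell_id = l, area = n, mean_intensity = s / n)
  }))
}

# Textbook Welch t-test p-value.
oracle_welch_p <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  2 * pt(-abs(tstat), df)
}

# Pixel-centre membership of a rotated ellipse (re-derived for overlap
# audits of generated scenes).
oracle_ellipse_pixels <- function(nr, nc, cr, cc, a, b, theta) {
  idx <- which(matrix(TRUE, nr, nc))
  i <- (idx - 1) %% nr + 1; j <- (idx - 1) %/% nr + 1
  dy <- i - cr; dx <- j - cc
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  idx[(u / a)^2 + (v / b)^2 <= 1]
}

# Random small segmentation fixture: patchy foreground plus a few 2x2
# seeds at distinct spots.
random_seg_fixture <- function(seed) {
  set.seed(seed)
  nr <- sample(8:32, 1); nc <- sample(8:32, 1)
  fg <- matrix(runif(nr * nc) < 0.65, nr, nc)
  k <- sample(1:4, 1)
  seeds <- matrix(0L, nr, nc)
  spots <- sample(which(matrix(TRUE, nr - 1, nc - 1)), k)
  for (l in seq_len(k)) {
    i <- (spots[l] - 1) %% (nr - 1) + 1; j <- (spots[l] - 1) %/% (nr - 1) + 1
    if (any(seeds[i:(i + 1), j:(j + 1)] > 0)) next
    seeds[i:(i + 1), j:(j + 1)] <- l
  }
  list(foreground = fg, seeds = seeds)
}

# Small rendered scene used by several suites.
small_scene <- function(n_cells = 8, shape = c(256, 256), q = 0.7,
                        seed = 42, gaussian_sd = NULL, jitter = 0.05) {
  field <- generate_cell_field(
    n_cells, shape,
    geometry = geometry_params(cyto_axis_range = c(14, 20)),
    intensity = intensity_params(base_jitter_sd = jitter),
    quench_factor = q, group = "g", seed = seed)
  img <- render_channels(field, gaussian_sd = gaussian_sd, seed = seed + 1)
  list(field = field, img = img)
}
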