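# Independent brute-force oracles used to verify the measurement code.
# These deliberately share no code with the package internals: everything
# is computed by naive per-pixel loops.

# Naive step-sum path length (1 orthogonal, sqrt(2) diagonal).
oracle_path_length <- function(path) {
  total <- 0
  for (i in seq_len(nrow(path) - 1L)) {
    dr <- abs(path[i + 1L, 1L] - path[i, 1L])
    dc <- abs(path[i + 1L, 2L] - path[i, 2L])
    total <- total + if (dr == 1L && dc == 1L) sqrt(2) else 1
  }
  total
}

# Every pixel within Chebyshev distance <= d of some path pixel, by
# scanning the whole image.
oracle_band <- function(path, d, shape) {
  band <- matrix(0L, shape[1L], shape[2L])
  for (r in seq_len(shape[1L])) for (c in seq_len(shape[2L])) {
    for (i in seq_len(nrow(path))) {
      if (max(abs(r - path[i, 1L]), abs(c - path[i, 2L])) <= d) {
        band[r, c] <- 1L
        break
      }
    }
  }
  band
}

# Nearest path index of a pixel (squared Euclidean, ties to the lower
# path index).
oracle_nearest_index <- function(r, c, path) {
  best <- Inf
  bi <- 0L
  for (i in seq_len(nrow(path))) {
    d2 <- (r - path[i, 1L])^2 + (c - path[i, 2L])^2
    if (d2 < best) { best <- d2; bi <- i }
  }
  bi
}

# Full primary-measure enumeration: band by scan, per-band-pixel nearest
# path index, covered runs by rle, all nine fields by direct loops.
oracle_primary <- function(path, d, img, thr) {
  shape <- dim(img)
  band <- oracle_band(path, d, shape)
  bp <- which(band == 1L, arr.ind = TRUE)
  n <- nrow(path)
  covered <- rep(FALSE, n)
  marker_area <- 0L
  marker_intensity <- 0
  idx <- integer(nrow(bp))
  for (k in seq_len(nrow(bp))) {
    idx[k] <- oracle_nearest_index(bp[k, 1L], bp[k, 2L], path)
    if (img[bp[k, 1L], bp[k, 2L]] > thr) {
      covered[idx[k]] <- TRUE
      marker_area <- marker_area + 1L
      marker_intensity <- marker_intensity + img[bp[k, 1L], bp[k, 2L]]
    }
  }
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(starts[r$values], ends[r$values])
  fjc <- 0
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs)))
      fjc <- fjc + oracle_path_length(path[runs[i, 1L]:runs[i, 2L], ,
                                           drop = FALSE])
    lo <- min(runs[, 1L]); hi <- max(runs[, 2L])
    jc <- oracle_path_length(path[lo:hi, , drop = FALSE])
    sjl <- sqrt(sum((path[lo, ] - path[hi, ])^2))
    jarea <- sum(idx >= lo & idx <= hi)
  } else {
    jc <- sjl <- jarea <- 0
  }
  list(interface_contour = oracle_path_length(path),
       straight_interface_length = sqrt(sum((path[1L, ] - path[n, ])^2)),
       interface_area = nrow(bp),
       junction_contour = jc,
       straight_junction_length = sjl,
       junction_area = jarea,
       fragmented_junction_contour = fjc,
       marker_area = marker_area,
       marker_intensity = marker_intensity)
}

# Random 8-connected simple path: a strictly monotone staircase walk
# (every step advances down and/or right, so no pixel repeats and
# consecutive pixels are always 8-neighbours).
random_path <- function(shape, len) {
  len <- min(len, min(shape) - 6L)
  r <- sample(seq(3L, shape[1L] - len - 2L), 1L)
  c <- sample(seq(3L, shape[2L] - len - 2L), 1L)
  path <- matrix(0L, len, 2L)
  path[1L, ] <- c(r, c)
  for (i in 2L:len) {
    step <- sample(1:3, 1L)   # 1 = down, 2 = right, 3 = diagonal
    r <- r + as.integer(step != 2L)
    c <- c + as.integer(step != 1L)
    path[i, ] <- c(r, c)
  }
  path
}

# Two-sided permutation test for a difference in means.
perm_test <- function(x, y, n_perm = 2000L) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    s <- sample(length(pool), nx)
    if (abs(mean(pool[s]) - mean(pool[-s])) >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

# Small random test image.
random_image <- function(shape, bit_depth = 8L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  raster_image(matrix(sample(0:(2^bit_depth - 1), prod(shape),
                             replace = TRUE),
                      shape[1L], shape[2L]), bit_depth)
}

# Shared small clean scene (re-used across tests to keep runtime down).
scene_cache <- new.env()
cached_scene <- function(key, spec) {
  if (is.null(scene_cache[[key]]))
    scene_cache[[key]] <- generate_monolayer(spec)
  scene_cache[[key]]
}
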