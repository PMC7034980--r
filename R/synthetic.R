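#' Specification of a synthetic monolayer scene
#'
#' Describes the geometry and photometry of a simulated epithelial or
#' endothelial monolayer rendered by [generate_monolayer()]. Defaults
#' emulate a clean, well-spread epithelial sheet: ~25 cells in a 384 x 384
#' 8-bit field, continuous junctional staining of width 3 px at 200 A.U.
#' over a 10 A.U. cytoplasmic background, no undulation, no noise.
#'
#' Presets adjust the phenotype:
#' \describe{
#'   \item{linear_epithelial}{straight, taut, fully covered junctions.}
#'   \item{undulated}{sinusoidal interface undulation (amplitude 2.5 px,
#'     period 24 px), as seen when junctions lose tension.}
#'   \item{zigzag_endothelial}{triangular-wave interfaces (amplitude 3 px,
#'     period 16 px), the jagged VE-cadherin morphology.}
#'   \item{dotted_disc}{fragmented, dotted staining (coverage 0.45) of
#'     brighter clusters, reminiscent of intercalated-disc markers.}
#' }
#'
#' @param preset phenotype preset name.
#' @param width,height image size in pixels.
#' @param n_cells number of cells (`>= 2`).
#' @param seed integer RNG seed; a fixed seed gives a byte-identical scene.
#' @param staining_width stained boundary width in pixels (`>= 1`).
#' @param staining_intensity,background_intensity A.U. within bit depth.
#' @param noise_sigma additive Gaussian noise sigma (A.U.).
#' @param coverage_fraction fraction of each interface's arc length covered
#'   by staining, in `[0, 1]`.
#' @param undulation_amplitude,undulation_period sinusoidal normal
#'   displacement of interfaces, px.
#' @param wave `"sine"` or `"triangle"` undulation waveform.
#' @param fragment_length target length of individual staining fragments (dots), px.
#' @param min_edge minimum interior interface length enforced by the
#'   generator (re-sampling seeds), px; keeps corners resolvable.
#' @param bit_depth 8 or 16.
#' @param expressing_fraction fraction of cells marked positive in the
#'   expression-mask channel (0 = no mask generated).
#' @param marker2 optional list of overrides (`staining_intensity`,
#'   `coverage_fraction`, `staining_width`, `fragment_length`) for a second
#'   co-registered marker channel; `NULL` = single channel.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(preset = c("linear_epithelial", "undulated",
                                  "zigzag_endothelial", "dotted_disc"),
                       width = 384L, height = 384L, n_cells = 25L,
                       seed = 1L, staining_width = 3,
                       staining_intensity = 200, background_intensity = 10,
                       noise_sigma = 0, coverage_fraction = 1,
                       undulation_amplitude = 0, undulation_period = 24,
                       wave = "sine", fragment_length = 10, min_edge = 12,
                       bit_depth = 8L, expressing_fraction = 0,
                       marker2 = NULL) {
  preset <- match.arg(preset)
  call_args <- names(match.call())[-1L]
  defaults <- switch(preset,
    linear_epithelial = list(),
    undulated = list(undulation_amplitude = 2.5, undulation_period = 24),
    zigzag_endothelial = list(undulation_amplitude = 3,
                              undulation_period = 16, wave = "triangle"),
    dotted_disc = list(coverage_fraction = 0.45, staining_intensity = 230,
                       fragment_length = 6))
  spec <- list(preset = preset, width = as.integer(width),
               height = as.integer(height), n_cells = as.integer(n_cells),
               seed = as.integer(seed), staining_width = staining_width,
               staining_intensity = staining_intensity,
               background_intensity = background_intensity,
               noise_sigma = noise_sigma,
               coverage_fraction = coverage_fraction,
               undulation_amplitude = undulation_amplitude,
               undulation_period = undulation_period, wave = wave,
               fragment_length = fragment_length, min_edge = min_edge,
               bit_depth = as.integer(bit_depth),
               expressing_fraction = expressing_fraction, marker2 = marker2)
  # preset defaults yield to explicitly supplied arguments
  for (nm in names(defaults))
    if (!nm %in% call_args) spec[[nm]] <- defaults[[nm]]
  if (spec$n_cells < 2L) stop("'n_cells' must be >= 2")
  if (spec$coverage_fraction < 0 || spec$coverage_fraction > 1)
    stop("'coverage_fraction' must lie in [0, 1]")
  if (spec$staining_width < 1) stop("'staining_width' must be >= 1")
  mx <- 2^spec$bit_depth - 1
  if (spec$staining_intensity > mx || spec$background_intensity > mx)
    stop("intensities must fit the bit depth")
  structure(spec, class = "scene_spec")
}

## ---- geometry: seeds, Delaunay, Voronoi -----------------------------------

# Seed placement: jittered hexagonal lattice followed by Lloyd relaxation
# toward a centroidal tessellation. A confluent monolayer is close to a
# relaxed honeycomb — near-uniform cell sizes, tricellular vertices around
# 120 degrees — and this initialization reproduces that while the jitter
# keeps every scene distinct.
sample_seeds <- function(n, h, w, lloyd_iters = 4L, grid_step = 3L) {
  s <- sqrt(h * w / n * 2 / sqrt(3))        # hex lattice spacing
  rows <- max(1L, round(h / (s * sqrt(3) / 2)))
  cols <- max(1L, ceiling(n / rows))
  while (rows * cols < n) cols <- cols + 1L
  pts <- matrix(NA_real_, rows * cols, 2L)
  k <- 0L
  for (i in seq_len(rows)) for (j in seq_len(cols)) {
    k <- k + 1L
    pts[k, ] <- c((i - 0.5) * h / rows,
                  (j - 0.5 + 0.25 * (-1)^i) * w / cols)
  }
  if (nrow(pts) > n)
    pts <- pts[sort(sample.int(nrow(pts), n)), , drop = FALSE]
  pts <- pts + matrix(stats::runif(2L * n, -0.22, 0.22), n, 2L) *
    rep(c(h / rows, w / cols), each = n)
  pts[, 1L] <- pmin(pmax(pts[, 1L], 4), h - 3)
  pts[, 2L] <- pmin(pmax(pts[, 2L], 4), w - 3)
  # Lloyd relaxation on a coarse pixel grid (centroids are insensitive to
  # the sampling step; the full-resolution label map is computed once later)
  gr <- as.matrix(expand.grid(row = seq(1, h, by = grid_step),
                              col = seq(1, w, by = grid_step)))
  for (it in seq_len(lloyd_iters)) {
    d2 <- outer(gr[, 1L], pts[, 1L], `-`)^2 + outer(gr[, 2L], pts[, 2L], `-`)^2
    lab <- max.col(-d2, ties.method = "first")
    for (i in seq_len(n)) {
      sel <- lab == i
      if (any(sel)) pts[i, ] <- colMeans(gr[sel, , drop = FALSE])
    }
  }
  pts
}

# Label every pixel by its nearest seed (Euclidean). Returns an h x w
# integer matrix with labels 1..n (no zero pixels).
nearest_seed_labels <- function(seeds, h, w) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  best <- matrix(Inf, h, w)
  lab <- matrix(1L, h, w)
  for (i in seq_len(nrow(seeds))) {
    d2 <- (rows - seeds[i, 1L])^2 + (cols - seeds[i, 2L])^2
    sel <- d2 < best
    best[sel] <- d2[sel]
    lab[sel] <- i
  }
  lab
}

# Per-cell count of owned pixels in the outermost 2-px image band (cheap
# border-cell test evaluated on the band only, not the full label map).
band_pixel_counts <- function(seeds, h, w) {
  band <- rbind(cbind(rep(c(1L, 2L, h - 1L, h), each = w), rep(seq_len(w), 4L)),
                cbind(rep(seq_len(h), 4L), rep(c(1L, 2L, w - 1L, w), each = h)))
  d2 <- outer(band[, 1L], seeds[, 1L], `-`)^2 +
    outer(band[, 2L], seeds[, 2L], `-`)^2
  tabulate(max.col(-d2, ties.method = "first"), nbins = nrow(seeds))
}

band_border_cells <- function(seeds, h, w) {
  band_pixel_counts(seeds, h, w) > 0L
}

circumcenter <- function(p1, p2, p3) {
  d <- 2 * (p1[1L] * (p2[2L] - p3[2L]) + p2[1L] * (p3[2L] - p1[2L]) +
              p3[1L] * (p1[2L] - p2[2L]))
  if (abs(d) < 1e-9) return(NULL)
  s1 <- sum(p1^2); s2 <- sum(p2^2); s3 <- sum(p3^2)
  r <- (s1 * (p2[2L] - p3[2L]) + s2 * (p3[2L] - p1[2L]) +
          s3 * (p1[2L] - p2[2L])) / d
  c0 <- (s1 * (p3[1L] - p2[1L]) + s2 * (p1[1L] - p3[1L]) +
           s3 * (p2[1L] - p1[1L])) / d
  c(r, c0)
}

# Brute-force Delaunay triangulation: a triple is Delaunay iff its open
# circumdisc contains no other seed. O(n^4) worst case but exact and ample
# at the <= 60 seeds this generator uses.
delaunay_triangles <- function(pts) {
  n <- nrow(pts)
  tri <- list()
  for (i in seq_len(n - 2L)) for (j in (i + 1L):(n - 1L)) {
    for (k in (j + 1L):n) {
      cc <- circumcenter(pts[i, ], pts[j, ], pts[k, ])
      if (is.null(cc)) next
      r2 <- sum((pts[i, ] - cc)^2)
      d2 <- (pts[, 1L] - cc[1L])^2 + (pts[, 2L] - cc[2L])^2
      if (all(d2 >= r2 - 1e-7 | seq_len(n) %in% c(i, j, k)))
        tri[[length(tri) + 1L]] <- list(v = c(i, j, k), cc = cc)
    }
  }
  tri
}

# Liang-Barsky clipping of segment p->q to the rectangle [1,h] x [1,w].
clip_segment <- function(p, q, h, w) {
  d <- q - p
  t0 <- 0; t1 <- 1
  for (side in 1:4) {
    pp <- switch(side, -d[1L], d[1L], -d[2L], d[2L])
    qq <- switch(side, p[1L] - 1, h - p[1L], p[2L] - 1, w - p[2L])
    if (abs(pp) < 1e-12) { if (qq < 0) return(NULL) } else {
      t <- qq / pp
      if (pp < 0) { if (t > t1) return(NULL); if (t > t0) t0 <- t }
      else { if (t < t0) return(NULL); if (t < t1) t1 <- t }
    }
  }
  rbind(p + t0 * d, p + t1 * d)
}

# Voronoi diagram (as edges dual to the Delaunay edges) clipped to the
# image rectangle. Returns vertex matrix and an edge list with flanking
# cell ids.
voronoi_geometry <- function(pts, h, w) {
  tri <- delaunay_triangles(pts)
  edge_key <- function(a, b) paste(min(a, b), max(a, b))
  emap <- new.env(hash = TRUE)
  for (t in seq_along(tri)) {
    v <- tri[[t]]$v
    for (pair in list(v[1:2], v[2:3], v[c(1, 3)])) {
      ky <- edge_key(pair[1L], pair[2L])
      emap[[ky]] <- c(if (!is.null(emap[[ky]])) emap[[ky]], t)
    }
  }
  big <- 4 * (h + w)
  edges <- list()
  for (ky in ls(emap)) {
    ts <- emap[[ky]]
    cells <- as.integer(strsplit(ky, " ")[[1L]])
    if (length(ts) == 2L) {
      p <- tri[[ts[1L]]]$cc; q <- tri[[ts[2L]]]$cc
    } else {
      p <- tri[[ts[1L]]]$cc
      a <- pts[cells[1L], ]; b <- pts[cells[2L], ]
      m <- (a + b) / 2
      dir <- c(-(b - a)[2L], (b - a)[1L])
      dir <- dir / sqrt(sum(dir^2))
      other <- setdiff(tri[[ts[1L]]]$v, cells)
      if (sum(dir * (m - pts[other, ])) < 0) dir <- -dir
      q <- p + big * dir
    }
    seg <- clip_segment(p, q, h, w)
    if (is.null(seg)) next
    len <- sqrt(sum((seg[2L, ] - seg[1L, ])^2))
    if (len < 1) next
    edges[[length(edges) + 1L]] <-
      list(cells = cells, from = seg[1L, ], to = seg[2L, ],
           from_in = all(abs(seg[1L, ] - p) < 1e-9),
           to_in = length(ts) == 2L && all(abs(seg[2L, ] - q) < 1e-9))
  }
  verts <- unique(do.call(rbind, lapply(tri, function(t) round(t$cc, 6))))
  inside <- verts[, 1L] >= 1 & verts[, 1L] <= h &
    verts[, 2L] >= 1 & verts[, 2L] <= w
  list(vertices = verts[inside, , drop = FALSE], edges = edges)
}

## ---- curve construction ----------------------------------------------------

# Dense polyline (step ~0.25 px) of a Voronoi edge with sinusoidal or
# triangular normal undulation, enveloped to vanish at both endpoints so
# corners stay exactly at the Voronoi vertices.
undulate_edge <- function(from, to, amplitude, period, wave, phase) {
  v <- to - from
  len <- sqrt(sum(v^2))
  nsamp <- max(2L, ceiling(len / 0.25) + 1L)
  s <- seq(0, len, length.out = nsamp)
  u <- v / len
  nrm <- c(-u[2L], u[1L])
  if (amplitude > 0) {
    arg <- 2 * pi * s / period + phase
    waveval <- if (wave == "triangle") (2 / pi) * asin(sin(arg)) else sin(arg)
    disp <- amplitude * waveval * sin(pi * s / len)
  } else disp <- numeric(nsamp)
  base <- cbind(from[1L] + s * u[1L], from[2L] + s * u[2L])
  pts <- base + outer(disp, nrm)
  seglen <- sqrt(rowSums(diff(pts)^2))
  list(points = pts, s = c(0, cumsum(seglen)), arc_length = sum(seglen))
}

# Split [0, L] into covered intervals realizing a coverage fraction:
# staining fragments of roughly `fragment_length`, one per equal-length
# block, jittered within its block with at least a 2-px margin so every
# gap is resolvable at raster scale. Returns an m x 2 matrix of covered
# (start, end) arc positions whose lengths sum to coverage * L exactly.
covered_intervals <- function(L, coverage, fragment_length) {
  if (coverage >= 1) return(matrix(c(0, L), 1L))
  if (coverage <= 0) return(matrix(numeric(0), 0L, 2L))
  f <- max(1L, round(coverage * L / fragment_length))
  # blocks must fit fragment + 2 px of gap margin on either side
  while (f > 1L && (L / f - coverage * L / f) < 4) f <- f - 1L
  frag <- coverage * L / f
  block <- L / f
  covered <- matrix(0, f, 2L)
  for (i in seq_len(f)) {
    lo <- (i - 1) * block
    slack <- block - frag
    start <- lo + stats::runif(1, min(2, slack / 2),
                               max(slack - min(2, slack / 2), 1e-9))
    covered[i, ] <- c(start, start + frag)
  }
  covered
}

# Stamp disc-brush staining along the covered stretches of an edge curve.
# Internal fragment ends are shrunk by the brush radius less 0.4 px:
# the slight overhang past each programmed boundary compensates the
# one-step-per-run quantization of raster run measurement (a run of m
# pixels measures m - 1 steps) so a painted interval of length l measures
# l in expectation. The 0.4 px end calibration was fixed against the
# cross-section covering rule on straight raster test strips.
stamp_edge <- function(canvas, curve, intervals, width, intensity) {
  r <- width / 2
  h <- nrow(canvas); w <- ncol(canvas)
  off <- as.matrix(expand.grid(dr = -ceiling(r):ceiling(r),
                               dc = -ceiling(r):ceiling(r)))
  off <- off[off[, 1L]^2 + off[, 2L]^2 <= r^2 + 1e-9, , drop = FALSE]
  L <- curve$arc_length
  stamped <- integer(0)
  for (i in seq_len(nrow(intervals))) {
    a <- intervals[i, 1L]; b <- intervals[i, 2L]
    a2 <- if (a > 1e-9) a + r - 0.4 else a
    b2 <- if (b < L - 1e-9) b - r + 0.4 else b
    if (b2 <= a2) { a2 <- (a + b) / 2; b2 <- a2 }
    sel <- which(curve$s >= a2 - 1e-9 & curve$s <= b2 + 1e-9)
    if (!length(sel)) next
    ctr <- round(curve$points[sel, , drop = FALSE])
    ctr <- unique(ctr)
    for (j in seq_len(nrow(ctr))) {
      rr <- ctr[j, 1L] + off[, 1L]
      cc <- ctr[j, 2L] + off[, 2L]
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      stamped <- c(stamped, (cc[ok] - 1L) * h + rr[ok])
    }
  }
  stamped <- unique(stamped)
  canvas[stamped] <- pmax(canvas[stamped], intensity)
  list(canvas = canvas, stamp_idx = stamped)
}

## ---- scene generation ------------------------------------------------------

#' Generate a synthetic monolayer image with exact ground truth
#'
#' Renders a Voronoi tessellation of `n_cells` seed points (dart-throwing
#' placement, Lloyd relaxation, interior interfaces shorter than
#' `min_edge` px rejected by re-sampling) as a junctional staining image:
#' each interior Voronoi edge becomes a staining band of
#' `staining_width`, optionally undulated by a sinusoidal (or triangular)
#' normal displacement that vanishes at the vertices, optionally fragmented
#' to a programmed `coverage_fraction`, over a uniform cytoplasmic
#' background, with optional additive Gaussian noise. The returned ground
#' truth records everything the renderer knew: seed points, Voronoi
#' vertices, per-interface continuous arc length, programmed coverage and
#' covered-interval extents, the stamped marker pixels, the pre-noise
#' image, and the per-pixel cell label map.
#'
#' @param spec a [scene_spec()].
#' @return a `monolayer_scene`: list with `image` (noisy render), `marker2`
#'   (or NULL), `expression_mask` (or NULL), `truth`, `spec`.
#' @export
generate_monolayer <- function(spec) {
  if (!inherits(spec, "scene_spec")) stop("'spec' must be a scene_spec")
  old <- local_seed(spec$seed)
  on.exit(restore_seed(old))
  h <- spec$height; w <- spec$width
  # keep re-sampling until every measurable (interior) interface is at
  # least min_edge long; fall back to the best attempt seen
  best <- NULL
  best_min <- -Inf
  for (attempt in seq_len(80L)) {
    seeds <- sample_seeds(spec$n_cells, h, w)
    geo <- voronoi_geometry(seeds, h, w)
    bcount <- band_pixel_counts(seeds, h, w)
    bc <- bcount > 0L
    # a cell entering the border band by only a sliver is ambiguous at
    # raster scale; demand cells be clearly interior or clearly border
    sliver <- any(bcount > 0L & bcount < 25L)
    interior_lens <- vapply(geo$edges, function(e) {
      if (e$from_in && e$to_in && !any(bc[e$cells]))
        sqrt(sum((e$to - e$from)^2)) else Inf
    }, numeric(1))
    mn <- suppressWarnings(min(interior_lens))
    if (sliver) mn <- min(mn, 0)
    # vertices delimiting measurable interfaces must not have any short
    # incident edge (a nearly-degenerate neighbouring vertex would merge
    # with the corner at raster scale and displace it), and arms must meet
    # at open angles: tricellular junctions of a relaxed monolayer are
    # near 120 degrees, and an acute fork displaces the thinned branch
    # point from the true vertex
    if (is.finite(mn) && mn >= spec$min_edge) {
      ivert <- do.call(rbind, lapply(
        Filter(function(e) e$from_in && e$to_in && !any(bc[e$cells]),
               geo$edges),
        function(e) rbind(e$from, e$to)))
      if (!is.null(ivert)) {
        ivert <- unique(round(ivert, 6))
        for (k in seq_len(nrow(ivert))) {
          v <- ivert[k, ]
          dirs <- list()
          shortinc <- FALSE
          for (e in geo$edges) {
            dfrom <- sqrt(sum((e$from - v)^2))
            dto <- sqrt(sum((e$to - v)^2))
            if (min(dfrom, dto) >= 0.5) next
            len <- sqrt(sum((e$to - e$from)^2))
            if (len < 0.67 * spec$min_edge) { shortinc <- TRUE; break }
            u <- if (dfrom < 0.5) e$to - e$from else e$from - e$to
            dirs[[length(dirs) + 1L]] <- u / len
          }
          if (shortinc) { mn <- min(mn, 1); break }
          if (length(dirs) >= 2L) {
            for (a in seq_len(length(dirs) - 1L))
              for (b in (a + 1L):length(dirs)) {
                ang <- acos(pmin(1, pmax(-1, sum(dirs[[a]] * dirs[[b]]))))
                if (ang < 75 * pi / 180) { shortinc <- TRUE }
              }
          }
          if (shortinc) { mn <- min(mn, 1); break }
        }
      }
    }
    if (mn > best_min) {
      best_min <- mn
      best <- list(seeds = seeds, geo = geo)
    }
    if (mn >= spec$min_edge) break
  }
  seeds <- best$seeds
  geo <- best$geo
  labels <- nearest_seed_labels(seeds, h, w)
  border_cells <- rep(FALSE, spec$n_cells)
  band <- unique(c(labels[c(1:2, (h - 1):h), ], labels[, c(1:2, (w - 1):w)]))
  border_cells[band] <- TRUE

  canvas <- matrix(0, h, w)
  edges <- vector("list", length(geo$edges))
  for (i in seq_along(geo$edges)) {
    e <- geo$edges[[i]]
    phase <- stats::runif(1, 0, 2 * pi)
    curve <- undulate_edge(e$from, e$to, spec$undulation_amplitude,
                           spec$undulation_period, spec$wave, phase)
    ivals <- covered_intervals(curve$arc_length, spec$coverage_fraction,
                               spec$fragment_length)
    st <- stamp_edge(canvas, curve, ivals, spec$staining_width,
                     spec$staining_intensity)
    canvas <- st$canvas
    path <- rasterize_polyline(curve$points)
    covered_len <- if (nrow(ivals)) sum(ivals[, 2L] - ivals[, 1L]) else 0
    edges[[i]] <- list(
      cells = e$cells, from = e$from, to = e$to,
      interior = e$from_in && e$to_in &&
        !any(border_cells[e$cells]),
      arc_length = curve$arc_length,
      coverage = covered_len / curve$arc_length,
      covered_intervals = ivals,
      path = path, stamp_idx = st$stamp_idx, phase = phase)
  }
  clean <- pmax(canvas, spec$background_intensity)
  clean_img <- raster_image(pmin(clean, 2^spec$bit_depth - 1),
                            spec$bit_depth)
  image <- if (spec$noise_sigma > 0)
    add_gaussian_noise(clean_img, spec$noise_sigma,
                       seed = spec$seed + 7919L)
  else clean_img

  marker2 <- clean2 <- NULL
  if (!is.null(spec$marker2)) {
    m2 <- utils::modifyList(
      list(staining_intensity = spec$staining_intensity,
           coverage_fraction = spec$coverage_fraction,
           staining_width = spec$staining_width,
           fragment_length = spec$fragment_length,
           noise_sigma = spec$noise_sigma), spec$marker2)
    canvas2 <- matrix(0, h, w)
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      curve <- undulate_edge(e$from, e$to, spec$undulation_amplitude,
                             spec$undulation_period, spec$wave, e$phase)
      ivals <- covered_intervals(curve$arc_length, m2$coverage_fraction,
                                 m2$fragment_length)
      st <- stamp_edge(canvas2, curve, ivals, m2$staining_width,
                       m2$staining_intensity)
      canvas2 <- st$canvas
      edges[[i]]$stamp_idx2 <- st$stamp_idx
    }
    clean2 <- raster_image(pmin(pmax(canvas2, spec$background_intensity),
                                2^spec$bit_depth - 1), spec$bit_depth)
    marker2 <- if (m2$noise_sigma > 0)
      add_gaussian_noise(clean2, m2$noise_sigma, seed = spec$seed + 104729L)
    else clean2
  }

  expressing <- NULL
  expression_mask <- NULL
  if (spec$expressing_fraction > 0) {
    expressing <- rep(FALSE, spec$n_cells)
    k <- max(1L, round(spec$expressing_fraction * spec$n_cells))
    expressing[sample.int(spec$n_cells, k)] <- TRUE
    expression_mask <- matrix(as.integer(expressing[labels]), h, w)
  }

  vtx <- geo$vertices
  truth <- list(seeds = seeds,
                vertices = data.frame(row = vtx[, 1L], col = vtx[, 2L]),
                edges = edges, labels = labels,
                border_cells = border_cells, expressing = expressing,
                clean_image = clean_img, clean_marker2 = clean2)
  structure(list(image = image, marker2 = marker2,
                 expression_mask = expression_mask,
                 truth = truth, spec = spec),
            class = "monolayer_scene")
}

#' @export
print.monolayer_scene <- function(x, ...) {
  n_int <- sum(vapply(x$truth$edges, `[[`, logical(1), "interior"))
  cat(sprintf(paste0("<monolayer_scene> %d x %d, %d cells, %d interfaces ",
                     "(%d interior), preset '%s'\n"),
              x$spec$height, x$spec$width, x$spec$n_cells,
              length(x$truth$edges), n_int, x$spec$preset))
  invisible(x)
}

#' Ground-truth skeleton and interfaces of a synthetic scene
#'
#' `truth_skeleton()` rasterizes the true interface curves into a
#' [skeleton_map] (the scene's perfect manual-edit outcome).
#' `truth_interfaces()` builds measurable interface records directly from
#' the true paths of interior interfaces, with junction classes taken from
#' the programmed expression states — the inputs a perfectly corrected
#' semi-automated session would produce.
#'
#' @param scene a `monolayer_scene`.
#' @return see description.
#' @export
truth_skeleton <- function(scene) {
  h <- scene$spec$height; w <- scene$spec$width
  m <- matrix(0L, h, w)
  for (e in scene$truth$edges) m[e$path] <- 1L
  skeletonize(m, prune_len = 0L)
}

#' @rdname truth_skeleton
#' @param interior_only keep only interfaces between non-border cells whose
#'   endpoints are true interior vertices.
#' @export
truth_interfaces <- function(scene, interior_only = TRUE) {
  out <- list()
  expressing <- scene$truth$expressing
  for (e in scene$truth$edges) {
    if (interior_only && !e$interior) next
    cls <- if (is.null(expressing)) "untyped"
    else c("control", "en", "ee")[sum(expressing[e$cells]) + 1L]
    out[[length(out) + 1L]] <-
      list(id = length(out) + 1L, corner_a = NA_integer_,
           corner_b = NA_integer_, path = e$path,
           cell_pair = sort(e$cells), junction_class = cls, flag = "",
           truth = list(arc_length = e$arc_length, coverage = e$coverage,
                        stamp_idx = e$stamp_idx))
  }
  out
}

#' Degrade an image to a target PSNR
#'
#' Adds Gaussian noise whose sigma is found by bisection so that the
#' measured PSNR against the original lands within 0.5 dB of `target_psnr`.
#' Used to probe the automatic-skeletonization quality gate (reliable above
#' about 22 dB).
#'
#' @param image a [raster_image].
#' @param target_psnr target in dB (`> 0`).
#' @param seed RNG seed for the noise.
#' @return the degraded [raster_image], with attribute `sigma`.
#' @export
degrade_scene <- function(image, target_psnr, seed = 1L) {
  stopifnot_scalar(target_psnr, "target_psnr", lo = 1e-6)
  lo <- 0.01
  hi <- 4 * max_value(image)
  f <- function(s) compute_psnr(image, add_gaussian_noise(image, s, seed))
  if (f(hi) > target_psnr + 0.5)
    stop("target PSNR unreachable: clipping floor is above the target")
  if (f(lo) < target_psnr - 0.5)
    stop("target PSNR unreachable: image cannot be made that clean")
  for (i in seq_len(60L)) {
    mid <- sqrt(lo * hi)
    p <- f(mid)
    if (abs(p - target_psnr) <= 0.25) { lo <- hi <- mid; break }
    if (p > target_psnr) lo <- mid else hi <- mid
    if (hi / lo < 1.0005) break
  }
  sigma <- sqrt(lo * hi)
  out <- add_gaussian_noise(image, sigma, seed)
  attr(out, "sigma") <- sigma
  out
}
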