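# Internal helpers shared across modules.

# 8-neighbourhood offsets in clockwise order starting north
# (used by thinning and crossing-number computations).
NB8 <- cbind(dr = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L),
             dc = c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L))

# Scoped RNG seeding: set the seed, return the previous .Random.seed so the
# caller can restore it (keeps package functions from perturbing user RNG
# state beyond their documented determinism contract).
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Shifted view of a matrix: out[i, j] = m[i + dr, j + dc], zero-padded.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

# Number of set 8-neighbours for every pixel of a 0/1 matrix.
neighbor_count8 <- function(m) {
  out <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(8L)) out <- out + shift_mat(m, NB8[k, 1L], NB8[k, 2L])
  out
}

# Crossing number A(p): 0->1 transitions around the 8-neighbourhood in
# clockwise order. A == 1 marks pixels whose removal keeps the local set
# connected (together with B >= 2).
crossing_number <- function(m) {
  nb <- lapply(seq_len(8L), function(k) shift_mat(m, NB8[k, 1L], NB8[k, 2L]))
  a <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(8L)) {
    nxt <- if (k == 8L) 1L else k + 1L
    a <- a + (nb[[k]] == 0) * (nb[[nxt]] == 1)
  }
  a
}

# Yokoi connectivity number for 8-connectivity: the number of 8-connected
# components of set neighbours that touch the centre. A pixel is 8-simple
# (deletable without changing topology) iff this equals 1. Uses the
# complement formula over the four 4-neighbours with their two following
# diagonal/orthogonal neighbours in counterclockwise ring order
# E, NE, N, NW, W, SW, S, SE.
yokoi8 <- function(m) {
  ring <- list(c(0L, 1L), c(-1L, 1L), c(-1L, 0L), c(-1L, -1L),
               c(0L, -1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  xb <- lapply(ring, function(o) 1 - shift_mat(m, o[1L], o[2L]))
  cnum <- matrix(0, nrow(m), ncol(m))
  for (k in c(1L, 3L, 5L, 7L)) {
    k1 <- k %% 8L + 1L
    k2 <- k1 %% 8L + 1L
    cnum <- cnum + (xb[[k]] - xb[[k]] * xb[[k1]] * xb[[k2]])
  }
  cnum
}

# 8-connected component labelling of a binary mask. EBImage::bwlabel is
# 4-connected; diagonal adjacencies are merged afterwards with union-find.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  unite <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal pairs: (i,j)-(i+1,j+1) and (i+1,j)-(i,j+1)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]
  a2 <- lab[-1L, -nc]; b2 <- lab[-nr, -1L]
  pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                 cbind(as.vector(a2), as.vector(b2)))
  pairs <- unique(pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                        pairs[, 1L] != pairs[, 2L], , drop = FALSE])
  for (i in seq_len(nrow(pairs))) unite(pairs[i, 1L], pairs[i, 2L])
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Bresenham 8-connected rasterization of the segment (r0,c0) -> (r1,c1),
# endpoints included. Returns an n x 2 matrix of (row, col).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- max(dr, dc) + 1L
  out <- matrix(0L, n, 2L)
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    out[i, ] <- c(r, c)
    if (r == r1 && c == c1) { out <- out[seq_len(i), , drop = FALSE]; break }
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  out
}

# Rasterize a polyline given as an n x 2 (row, col) matrix into an
# 8-connected pixel chain, duplicate-free at segment joins.
rasterize_polyline <- function(pts) {
  pts <- round(pts)
  if (nrow(pts) == 1L) return(matrix(as.integer(pts), 1L, 2L))
  segs <- vector("list", nrow(pts) - 1L)
  for (i in seq_len(nrow(pts) - 1L)) {
    s <- bresenham(pts[i, 1L], pts[i, 2L], pts[i + 1L, 1L], pts[i + 1L, 2L])
    if (i > 1L) s <- s[-1L, , drop = FALSE]
    segs[[i]] <- s
  }
  out <- do.call(rbind, segs)
  # drop consecutive duplicates (collinear joins)
  keep <- c(TRUE, rowSums(abs(diff(out))) > 0L)
  matrix(as.integer(out[keep, , drop = FALSE]), ncol = 2L)
}

# Chebyshev (chessboard) dilation of a binary mask by radius d: box brush of
# side 2d + 1, exactly the set of pixels within Chebyshev distance <= d.
dilate_chebyshev <- function(mask, d) {
  if (d == 0L) return((mask > 0) + 0L)
  out <- EBImage::dilate(mask > 0, EBImage::makeBrush(2L * d + 1L, "box"))
  m <- (as.numeric(out) > 0) + 0L
  dim(m) <- dim(mask)
  m
}

stopifnot_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop("'", name, "' must be a single value in [", lo, ", ", hi, "]")
  x
}
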