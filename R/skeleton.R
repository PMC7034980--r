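#' One-pixel-wide boundary skeleton
#'
#' A `skeleton_map` is a binary 0/1 matrix marking cell boundaries, thinned
#' so that no 2x2 block is fully set (the standard one-pixel-width
#' criterion), plus a per-pixel provenance matrix with codes 0 = off,
#' 1 = auto, 2 = added by an edit script, 3 = moved by ridge refinement.
#'
#' @param pixels binary matrix.
#' @param provenance optional integer matrix of the same shape.
#' @return object of class `skeleton_map`.
#' @export
skeleton_map <- function(pixels, provenance = NULL) {
  px <- (pixels > 0) + 0L
  dim(px) <- dim(pixels)
  if (is.null(provenance)) provenance <- px
  structure(list(pixels = px, provenance = provenance),
            class = "skeleton_map")
}

#' @export
print.skeleton_map <- function(x, ...) {
  cat(sprintf("<skeleton_map> %d x %d, %d boundary pixels\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' @export
dim.skeleton_map <- function(x) dim(x$pixels)

## ---- automatic edge detection -------------------------------------------

#' Detect cell boundary ridges in a junction-marker image
#'
#' Emulates the emboss-and-binarize boundary detection of the semi-automated
#' workflow: Gaussian blur to suppress pixel noise, unsharp sharpening to
#' emphasise ridges, then adaptive binarization of each pixel against the
#' mean of its local neighbourhood scaled by `binarize_threshold`. Connected
#' ridge fragments smaller than `min_object` pixels are discarded as noise
#' specks and small holes are closed with a 3x3 morphological closing.
#'
#' On a uniform image the pixel/local-mean ratio is 1 everywhere, so any
#' `binarize_threshold > 1` yields an empty edge map.
#'
#' @param image a [raster_image].
#' @param blur_radius Gaussian blur sigma in pixels (`>= 0`).
#' @param local_window odd window size (`>= 3`) of the averaging filter.
#' @param binarize_threshold a pixel is boundary when its sharpened
#'   intensity exceeds `binarize_threshold` times its local mean.
#' @param sharpen_amount unsharp-mask gain.
#' @param min_object minimum connected-fragment size kept, in pixels.
#' @return binary edge mask (0/1 matrix).
#' @export
detect_edges <- function(image, blur_radius = 2, local_window = 21L,
                         binarize_threshold = 1.3, sharpen_amount = 0.8,
                         min_object = 30L) {
  stopifnot_scalar(blur_radius, "blur_radius", 0)
  if (local_window %% 2L == 0L || local_window < 3L)
    stop("'local_window' must be odd and >= 3")
  x <- matrix(as.numeric(image), nrow(image), ncol(image))
  if (max(x) == min(x)) return(matrix(0L, nrow(x), ncol(x)))
  blurred <- if (blur_radius > 0) {
    b <- EBImage::gblur(x, sigma = blur_radius)
    matrix(as.numeric(b), nrow(x), ncol(x))
  } else x
  sharp <- blurred + sharpen_amount * (blurred - {
    b2 <- EBImage::gblur(blurred, sigma = max(2 * blur_radius, 1))
    matrix(as.numeric(b2), nrow(x), ncol(x))
  })
  box <- matrix(1 / local_window^2, local_window, local_window)
  localmean <- matrix(as.numeric(EBImage::filter2(blurred, box)),
                      nrow(x), ncol(x))
  edges <- (sharp > binarize_threshold * localmean) + 0L
  # close 1-px gaps, then drop speckle components
  edges <- EBImage::closing(edges > 0, EBImage::makeBrush(3L, "box"))
  edges <- (matrix(as.numeric(edges), nrow(x), ncol(x)) > 0) + 0L
  if (min_object > 1L && any(edges > 0)) {
    lab <- label8(edges)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object)
    edges <- (matrix(lab %in% keep, nrow(x), ncol(x))) + 0L
  }
  edges
}

## ---- thinning -------------------------------------------------------------

# One pass of Zhang-Suen deletion; step is 1 or 2. Vectorized over the image.
zs_pass <- function(m, step) {
  nb <- lapply(seq_len(8L), function(k) shift_mat(m, NB8[k, 1L], NB8[k, 2L]))
  # NB8 order: P2=N, P3=NE, P4=E, P5=SE, P6=S, P7=SW, P8=W, P9=NW
  b <- Reduce(`+`, nb)
  a <- matrix(0, nrow(m), ncol(m))
  for (k in seq_len(8L)) {
    nxt <- if (k == 8L) 1L else k + 1L
    a <- a + (nb[[k]] == 0) * (nb[[nxt]] == 1)
  }
  if (step == 1L) {
    c1 <- nb[[1L]] * nb[[3L]] * nb[[5L]]   # P2*P4*P6
    c2 <- nb[[3L]] * nb[[5L]] * nb[[7L]]   # P4*P6*P8
  } else {
    c1 <- nb[[1L]] * nb[[3L]] * nb[[7L]]   # P2*P4*P8
    c2 <- nb[[1L]] * nb[[5L]] * nb[[7L]]   # P2*P6*P8
  }
  del <- m == 1 & b >= 2 & b <= 6 & a == 1 & c1 == 0 & c2 == 0
  m[del] <- 0L
  m
}

# Number of set 8-neighbours and Yokoi connectivity of a single pixel,
# computed on the current matrix (used during sequential deletions).
local_simple <- function(m, r, c) {
  nr <- nrow(m); nc <- ncol(m)
  at <- function(rr, cc) if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc)
    m[rr, cc] else 0L
  ring <- c(at(r, c + 1L), at(r - 1L, c + 1L), at(r - 1L, c),
            at(r - 1L, c - 1L), at(r, c - 1L), at(r + 1L, c - 1L),
            at(r + 1L, c), at(r + 1L, c + 1L))
  xb <- 1L - ring
  cnum <- 0L
  for (k in c(1L, 3L, 5L, 7L)) {
    k1 <- k %% 8L + 1L
    k2 <- k1 %% 8L + 1L
    cnum <- cnum + xb[k] - xb[k] * xb[k1] * xb[k2]
  }
  c(simple = cnum == 1L, b = sum(ring))
}

# Remove one deletable pixel from every fully-set 2x2 block until none
# remain; deletable = 8-simple (Yokoi connectivity 1) and more than one
# neighbour (removal cannot disconnect or shorten the path).
squash_2x2 <- function(m) {
  repeat {
    nr <- nrow(m); nc <- ncol(m)
    blk <- m[-nr, -nc] & m[-1L, -nc] & m[-nr, -1L] & m[-1L, -1L]
    idx <- which(blk, arr.ind = TRUE)
    if (nrow(idx) == 0L) return(m)
    changed <- FALSE
    for (i in seq_len(nrow(idx))) {
      r <- idx[i, 1L]; c <- idx[i, 2L]
      cand <- rbind(c(r, c), c(r, c + 1L), c(r + 1L, c), c(r + 1L, c + 1L))
      for (j in seq_len(4L)) {
        rr <- cand[j, 1L]; cc <- cand[j, 2L]
        if (m[rr, cc] == 1L) {
          ls <- local_simple(m, rr, cc)
          if (ls[1L] == 1L && ls[2L] > 1L) {
            m[rr, cc] <- 0L
            changed <- TRUE
            break
          }
        }
      }
    }
    if (!changed) return(m)   # pathological block; give up rather than loop
  }
}

# Delete redundant staircase pixels: any pixel whose 8-neighbourhood set
# forms a single contiguous arc (crossing number 1) and that is not an
# endpoint can be removed without disconnecting the skeleton. Sequential
# scan with local recomputation, repeated until stable; yields a minimal
# 8-connected skeleton where only true branch points have >= 3 separated
# neighbours.
remove_redundant <- function(m) {
  repeat {
    cnum <- yokoi8(m)
    b <- neighbor_count8(m)
    cand <- which(m == 1 & cnum == 1 & b >= 2, arr.ind = TRUE)
    if (nrow(cand) == 0L) return(m)
    changed <- FALSE
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      ls <- local_simple(m, r, c)
      if (ls[1L] == 1L && ls[2L] >= 2L) {
        m[r, c] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) return(m)
  }
}

# Iteratively delete endpoint pixels (exactly one 8-neighbour) n times.
# Pixels on the outermost image rows/columns are protected: open boundary
# paths legitimately terminate at the image border.
prune_spurs <- function(m, n) {
  if (n <= 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  border <- matrix(FALSE, nr, nc)
  border[c(1L, nr), ] <- TRUE
  border[, c(1L, nc)] <- TRUE
  for (i in seq_len(n)) {
    b <- neighbor_count8(m)
    ends <- m == 1 & b == 1 & !border
    if (!any(ends)) break
    m[ends] <- 0L
  }
  m
}

#' Thin a binary edge mask to a one-pixel-wide skeleton
#'
#' Zhang-Suen morphological thinning preserving 8-connectivity, followed by
#' removal of isolated pixels, pruning of spurs shorter than `prune_len`,
#' and squashing of any residual fully-set 2x2 block. Idempotent on inputs
#' that are already one pixel wide (up to spur pruning).
#'
#' @param edges binary mask (matrix or output of [detect_edges()]).
#' @param prune_len spur-pruning length in pixels (thinning artifacts are a
#'   few pixels long; genuine short branches survive via corner editing).
#' @return a [skeleton_map].
#' @export
skeletonize <- function(edges, prune_len = 5L) {
  m <- (edges > 0) + 0L
  dim(m) <- dim(edges)
  # replicate-pad so thinning does not retract band ends that touch the
  # image border (open ends otherwise erode inward, merging border cells)
  pad <- 4L
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr + 2L * pad) - pad, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2L * pad) - pad, 1L), nc)
  m <- m[ri, ci]
  repeat {
    before <- m
    m <- zs_pass(m, 1L)
    m <- zs_pass(m, 2L)
    if (identical(m, before)) break
  }
  m <- m[pad + seq_len(nr), pad + seq_len(nc)]
  m <- squash_2x2(m)
  m <- remove_redundant(m)
  m <- prune_spurs(m, as.integer(prune_len))
  m[neighbor_count8(m) == 0] <- 0L   # isolated pixels
  skeleton_map(m)
}

## ---- scripted edits --------------------------------------------------------

#' Build an edit script
#'
#' An edit script is the reproducible stand-in for interactive skeleton
#' correction: an ordered list of edits, each `list(action =, polyline =)`
#' with `action` `"add"` (draw an 8-connected polyline into the skeleton)
#' or `"remove"` (clear skeleton pixels within Chebyshev distance 1 of the
#' polyline). Polylines are n x 2 (row, col) matrices; `add` needs at least
#' 2 points, `remove` at least 1.
#'
#' @param ... edits, each a list with elements `action` and `polyline`.
#' @return object of class `edit_script`.
#' @export
edit_script <- function(...) {
  edits <- list(...)
  if (length(edits) == 1L && is.null(edits[[1L]]$action) &&
      is.list(edits[[1L]]))
    edits <- edits[[1L]]
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    if (!e$action %in% c("add", "remove"))
      stop("edit ", i, ": action must be 'add' or 'remove'")
    pl <- e$polyline
    if (!is.matrix(pl) || ncol(pl) != 2L)
      stop("edit ", i, ": polyline must be an n x 2 (row, col) matrix")
    minpts <- if (e$action == "add") 2L else 1L
    if (nrow(pl) < minpts)
      stop("edit ", i, ": '", e$action, "' needs >= ", minpts, " points")
  }
  structure(edits, class = "edit_script")
}

#' Read / write edit scripts as structured text
#'
#' One edit per line: the action keyword followed by whitespace-separated
#' `row,col` pairs, e.g. `add 10,12 30,12`. Blank lines and lines starting
#' with `#` are ignored.
#'
#' @param path file path.
#' @param edits an [edit_script()].
#' @return `read_edit_script()` returns an `edit_script`.
#' @export
read_edit_script <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  edits <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "[[:space:]]+")[[1L]]
    action <- parts[1L]
    coords <- do.call(rbind, lapply(parts[-1L], function(p) {
      as.integer(strsplit(p, ",")[[1L]])
    }))
    list(action = action, polyline = coords)
  })
  edit_script(edits)
}

#' @rdname read_edit_script
#' @export
write_edit_script <- function(edits, path) {
  lines <- vapply(edits, function(e) {
    paste(e$action,
          paste(apply(e$polyline, 1L, function(p) paste0(p[1L], ",", p[2L])),
                collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Apply an edit script to a skeleton
#'
#' `add` edits rasterize their polyline into the skeleton (Bresenham,
#' 8-connected); `remove` edits clear all skeleton pixels within Chebyshev
#' distance 1 of the rasterized polyline. The result is re-thinned so the
#' one-pixel-width invariant holds, and provenance records added pixels.
#'
#' @param skeleton a [skeleton_map].
#' @param edits an [edit_script()].
#' @param prune_len spur pruning used in the re-thinning pass; default 0 so
#'   manual additions are never pruned away.
#' @return the edited [skeleton_map].
#' @export
apply_edits <- function(skeleton, edits, prune_len = 0L) {
  m <- skeleton$pixels
  prov <- skeleton$provenance
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_along(edits)) {
    e <- edits[[i]]
    pl <- e$polyline
    if (any(pl[, 1L] < 1L | pl[, 1L] > nr | pl[, 2L] < 1L | pl[, 2L] > nc))
      stop("edit ", i, ": coordinate outside image bounds")
    px <- rasterize_polyline(pl)
    if (e$action == "add") {
      m[px] <- 1L
      prov[px] <- 2L
    } else {
      line <- matrix(0L, nr, nc)
      line[px] <- 1L
      zone <- dilate_chebyshev(line, 1L)
      m[zone == 1L] <- 0L
      prov[zone == 1L] <- 0L
    }
  }
  out <- skeletonize(m, prune_len = prune_len)
  prov[out$pixels == 0L] <- 0L
  prov[out$pixels == 1L & prov == 0L] <- 1L
  skeleton_map(out$pixels, prov)
}

## ---- ridge refinement ------------------------------------------------------

#' Snap a skeleton onto the local intensity ridge
#'
#' Each skeleton pixel moves to the maximum-intensity pixel within its
#' `(2 * search_radius + 1)^2` neighbourhood. A pixel already attaining the
#' window maximum stays put (so a constant image is a fixed point); among
#' strictly brighter candidates ties are broken deterministically by
#' smallest (row, col). The moved
#' point set is dilated by 1 pixel to restore continuity and re-thinned. If
#' the re-thinned result changes the skeleton's connected-component count,
#' the original pixels are merged back in before a final thinning, which
#' preserves topology by construction.
#'
#' @param skeleton a [skeleton_map].
#' @param image the [raster_image] whose ridges to follow.
#' @param search_radius search half-width in pixels (`>= 1`).
#' @return the refined [skeleton_map].
#' @export
refine_skeleton <- function(skeleton, image, search_radius = 2L) {
  stopifnot_scalar(search_radius, "search_radius", 1)
  m <- skeleton$pixels
  if (!identical(dim(m), dim(image)))
    stop("skeleton and image shapes differ")
  pts <- which(m == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(skeleton)
  r <- as.integer(search_radius)
  nr <- nrow(m); nc <- ncol(m)
  img <- unclass(image)
  moved <- matrix(0L, nr, nc)
  offs <- as.matrix(expand.grid(dr = -r:r, dc = -r:r))
  # row-major scan of the window matches the smallest-(row, col) tie-break
  ord <- order(offs[, 1L], offs[, 2L])
  offs <- offs[ord, , drop = FALSE]
  for (i in seq_len(nrow(pts))) {
    rr <- pts[i, 1L] + offs[, 1L]
    cc <- pts[i, 2L] + offs[, 2L]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    vals <- img[cbind(rr[ok], cc[ok])]
    # a pixel already on the ridge stays put; otherwise first (row-major
    # scan) maximum = smallest-(row, col) tie-break
    if (img[pts[i, 1L], pts[i, 2L]] >= max(vals)) {
      moved[pts[i, 1L], pts[i, 2L]] <- 1L
    } else {
      k <- which.max(vals)
      moved[rr[ok][k], cc[ok][k]] <- 1L
    }
  }
  if (identical(moved, m)) return(skeleton)   # already on the ridge
  ncomp_before <- max(label8(m))
  out <- skeletonize(dilate_chebyshev(moved, 1L), prune_len = 0L)
  if (max(label8(out$pixels)) != ncomp_before) {
    merged <- (out$pixels | m) + 0L
    out <- skeletonize(dilate_chebyshev(merged, 1L), prune_len = 0L)
  }
  prov <- out$pixels * 3L
  prov[out$pixels == 1L & skeleton$pixels == 1L] <- skeleton$provenance[
    out$pixels == 1L & skeleton$pixels == 1L]
  skeleton_map(out$pixels, prov)
}
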