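#' Label cells as connected regions between boundaries
#'
#' Cells are the 4-connected components of the skeleton's complement
#' (4-connectivity prevents a cell from leaking through a diagonal step of
#' the 8-connected skeleton). Components that touch the image border within
#' `border_margin` pixels are flagged so that junctions of cells not fully
#' surrounded by neighbours can be excluded downstream.
#'
#' @param skeleton a [skeleton_map].
#' @param border_margin width in pixels of the border band used for the
#'   border-cell flag.
#' @return a `cell_label_map`: list with `labels` (integer matrix, 0 on the
#'   skeleton), `n_cells`, and `border` (logical per label).
#' @export
label_cells <- function(skeleton, border_margin = 2L) {
  m <- skeleton$pixels
  comp <- EBImage::bwlabel(m == 0L)            # 4-connected complement
  labels <- matrix(as.integer(comp), nrow(m), ncol(m))
  n <- max(labels)
  nr <- nrow(m); nc <- ncol(m)
  bm <- as.integer(border_margin)
  band <- labels[c(seq_len(min(bm, nr)), seq(max(1L, nr - bm + 1L), nr)), ]
  band2 <- labels[, c(seq_len(min(bm, nc)), seq(max(1L, nc - bm + 1L), nc))]
  border <- rep(FALSE, n)
  hit <- unique(c(band[band > 0L], band2[band2 > 0L]))
  border[hit] <- TRUE
  structure(list(labels = labels, n_cells = n, border = border),
            class = "cell_label_map")
}

#' @export
print.cell_label_map <- function(x, ...) {
  cat(sprintf("<cell_label_map> %d cells (%d border-touching)\n",
              x$n_cells, sum(x$border)))
  invisible(x)
}

# Distinct nonzero labels within Chebyshev distance `radius` of (r, c).
labels_near <- function(labels, r, c, radius) {
  nr <- nrow(labels); nc <- ncol(labels)
  rs <- max(1L, r - radius):min(nr, r + radius)
  cs <- max(1L, c - radius):min(nc, c + radius)
  v <- labels[rs, cs]
  sort(unique(v[v > 0L]))
}

#' Detect tricellular corners
#'
#' A corner is a meeting point of three or more cells. A skeleton pixel is a
#' corner candidate when at least 3 distinct cell labels occur within
#' Chebyshev distance `radius` of it; clusters of candidates closer than
#' `2 * radius` (Chebyshev, transitively) are merged into a single corner
#' placed at the cluster centroid snapped to the nearest skeleton pixel.
#' Corners are sorted by (row, col) and numbered from 1.
#'
#' @param skeleton a [skeleton_map].
#' @param labels a `cell_label_map` from [label_cells()] on this skeleton.
#' @param radius detection radius in pixels (`>= 1`).
#' @return data frame with columns `id`, `row`, `col`, `n_cells`, `source`,
#'   plus a list column `adjacent_cells`.
#' @export
detect_corners <- function(skeleton, labels, radius = 2L) {
  if (!identical(dim(skeleton$pixels), dim(labels$labels)))
    stop("skeleton and label map shapes differ")
  stopifnot_scalar(radius, "radius", 1)
  radius <- as.integer(radius)
  pts <- which(skeleton$pixels == 1L, arr.ind = TRUE)
  if (nrow(pts) == 0L) return(empty_corners())
  lab <- labels$labels
  ncand <- integer(nrow(pts))
  nearsets <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    s <- labels_near(lab, pts[i, 1L], pts[i, 2L], radius)
    nearsets[[i]] <- s
    ncand[i] <- length(s)
  }
  cand <- which(ncand >= 3L)
  if (length(cand) == 0L) return(empty_corners())
  # merge candidates within Chebyshev 2*radius (transitive closure)
  cpts <- pts[cand, , drop = FALSE]
  k <- length(cand)
  grp <- seq_len(k)
  dmax <- 2L * radius
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (max(abs(cpts[i, ] - cpts[j, ])) <= dmax) {
        gi <- grp[i]; gj <- grp[j]
        if (gi != gj) grp[grp == max(gi, gj)] <- min(gi, gj)
      }
    }
  }
  skel_pts <- pts
  # prefer the skeleton's true branch point (>= 3 separated arms, by the
  # crossing number) near the candidate centroid: it is the raster
  # analogue of the tricellular vertex
  branch <- crossing_number(skeleton$pixels) >= 3 & skeleton$pixels == 1L
  branch_pts <- which(branch, arr.ind = TRUE)
  groups <- unique(grp)
  out <- lapply(groups, function(g) {
    members <- which(grp == g)
    cen <- colMeans(cpts[members, , drop = FALSE])
    pos <- NULL
    if (nrow(branch_pts)) {
      d2b <- (branch_pts[, 1L] - cen[1L])^2 + (branch_pts[, 2L] - cen[2L])^2
      if (min(d2b) <= 16) {
        bestb <- which(d2b == min(d2b))
        bestb <- bestb[order(branch_pts[bestb, 1L],
                             branch_pts[bestb, 2L])][1L]
        pos <- branch_pts[bestb, ]
      }
    }
    if (is.null(pos)) {
      d2 <- (skel_pts[, 1L] - cen[1L])^2 + (skel_pts[, 2L] - cen[2L])^2
      best <- which(d2 == min(d2))
      best <- best[order(skel_pts[best, 1L], skel_pts[best, 2L])][1L]
      pos <- skel_pts[best, ]
    }
    adj <- sort(unique(unlist(nearsets[cand[members]])))
    list(row = pos[1L], col = pos[2L], adj = adj)
  })
  rows <- vapply(out, `[[`, numeric(1), "row")
  cols <- vapply(out, `[[`, numeric(1), "col")
  ord <- order(rows, cols)
  corners <- data.frame(id = seq_along(ord),
                        row = as.integer(rows[ord]),
                        col = as.integer(cols[ord]),
                        n_cells = vapply(out[ord], function(x) length(x$adj),
                                         integer(1)),
                        source = "auto",
                        stringsAsFactors = FALSE)
  corners$adjacent_cells <- lapply(out[ord], `[[`, "adj")
  corners
}

#' Refine corner positions by intersecting the arm midlines
#'
#' The thinned skeleton's branch point sits inside the junction blob where
#' the staining bands of the meeting interfaces merge, displaced a few
#' pixels from the true tricellular vertex. Away from the blob the skeleton
#' tracks the band midlines faithfully, so the vertex is re-estimated as
#' the least-squares intersection of straight lines fitted to the skeleton
#' arms in an annulus around the branch point, then snapped to the nearest
#' skeleton pixel (ties to smallest (row, col)) so corners stay on the
#' skeleton. Corners whose arms cannot be resolved (fewer than two arms, or
#' near-parallel arms) keep their original position.
#'
#' @param corners corner data frame from [detect_corners()].
#' @param skeleton the matching [skeleton_map].
#' @param image the junction-marker [raster_image] (unused by the line fit;
#'   accepted for interface stability).
#' @param threshold marker threshold (unused by the line fit).
#' @param r_in,r_out inner and outer Chebyshev radii of the fitting
#'   annulus, px.
#' @return the corner data frame with updated positions.
#' @export
refine_corner_positions <- function(corners, skeleton, image = NULL,
                                    threshold = NULL, r_in = 4L,
                                    r_out = 9L) {
  if (!nrow(corners)) return(corners)
  m <- skeleton$pixels
  nr <- nrow(m); nc <- ncol(m)
  skel_pts <- which(m == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(corners))) {
    p0 <- c(corners$row[i], corners$col[i])
    rs <- max(1L, p0[1L] - r_out):min(nr, p0[1L] + r_out)
    cs <- max(1L, p0[2L] - r_out):min(nc, p0[2L] + r_out)
    # only pixels connected to the corner through the local skeleton patch
    # belong to its arms (unrelated paths may cross the window)
    patch <- m[rs, cs]
    lab <- label8(patch)
    own <- lab[p0[1L] - rs[1L] + 1L, p0[2L] - cs[1L] + 1L]
    sub <- which(patch == 1L & lab == own, arr.ind = TRUE)
    pts <- cbind(rs[sub[, 1L]], cs[sub[, 2L]])
    dch <- pmax(abs(pts[, 1L] - p0[1L]), abs(pts[, 2L] - p0[2L]))
    ann <- pts[dch >= r_in, , drop = FALSE]
    if (nrow(ann) < 4L) next
    # cluster annulus pixels into arms (transitive 8-adjacency)
    k <- nrow(ann)
    grp <- seq_len(k)
    for (a in seq_len(k - 1L)) for (b in (a + 1L):k)
      if (max(abs(ann[a, ] - ann[b, ])) <= 1L) {
        g <- grp[c(a, b)]
        grp[grp == max(g)] <- min(g)
      }
    arms <- split(seq_len(k), grp)
    arms <- arms[vapply(arms, length, integer(1)) >= 2L]
    if (length(arms) < 2L) next
    # least-squares intersection of the arm lines: solve (sum n n^T) p =
    # sum n n^T a with n the unit normal of each fitted line
    A <- matrix(0, 2L, 2L)
    bvec <- c(0, 0)
    for (arm in arms) {
      ap <- ann[arm, , drop = FALSE]
      cen <- colMeans(ap)
      cv <- stats::cov(ap)
      ev <- eigen(cv, symmetric = TRUE)
      nrm <- ev$vectors[, 2L]           # normal = minor axis
      N <- outer(nrm, nrm)
      A <- A + N
      bvec <- bvec + N %*% cen
    }
    est <- tryCatch(as.numeric(solve(A, bvec)), error = function(e) NULL)
    if (is.null(est) || any(abs(est - p0) > r_out)) next
    d2 <- (skel_pts[, 1L] - est[1L])^2 + (skel_pts[, 2L] - est[2L])^2
    best <- which(d2 == min(d2))
    best <- best[order(skel_pts[best, 1L], skel_pts[best, 2L])][1L]
    corners$row[i] <- skel_pts[best, 1L]
    corners$col[i] <- skel_pts[best, 2L]
  }
  ord <- order(corners$row, corners$col)
  corners <- corners[ord, , drop = FALSE]
  corners$id <- seq_len(nrow(corners))
  rownames(corners) <- NULL
  corners
}

empty_corners <- function() {
  out <- data.frame(id = integer(0), row = integer(0), col = integer(0),
                    n_cells = integer(0), source = character(0),
                    stringsAsFactors = FALSE)
  out$adjacent_cells <- list()
  out
}

#' Manually adjust the corner set
#'
#' Manual corners stand in for interactive correction: additions must lie on
#' the skeleton (their adjacent cells are computed from the label map and may
#' number fewer than 3); removals drop existing corners by id. Ids are
#' renumbered stably by (row, col).
#'
#' @param corners corner data frame from [detect_corners()].
#' @param skeleton the [skeleton_map] the corners belong to.
#' @param labels the matching `cell_label_map`.
#' @param additions n x 2 (row, col) matrix of new corner positions.
#' @param removals integer ids to drop.
#' @param radius neighbourhood used to compute adjacent cells of additions.
#' @return the adjusted corner data frame.
#' @export
adjust_corners <- function(corners, skeleton, labels,
                           additions = NULL, removals = NULL, radius = 2L) {
  if (!is.null(removals) && length(removals)) {
    unknown <- setdiff(removals, corners$id)
    if (length(unknown))
      stop("unknown corner id(s): ", paste(unknown, collapse = ", "))
    corners <- corners[!corners$id %in% removals, , drop = FALSE]
  }
  if (!is.null(additions) && nrow(additions)) {
    for (i in seq_len(nrow(additions))) {
      r <- additions[i, 1L]; c <- additions[i, 2L]
      if (skeleton$pixels[r, c] != 1L)
        stop("manual corner ", i, " at (", r, ",", c, ") is off the skeleton")
      adj <- labels_near(labels$labels, r, c, as.integer(radius))
      add <- data.frame(id = NA_integer_, row = as.integer(r),
                        col = as.integer(c), n_cells = length(adj),
                        source = "manual", stringsAsFactors = FALSE)
      add$adjacent_cells <- list(adj)
      corners <- rbind(corners, add)
    }
  }
  ord <- order(corners$row, corners$col)
  corners <- corners[ord, , drop = FALSE]
  corners$id <- seq_len(nrow(corners))
  rownames(corners) <- NULL
  corners
}

## ---- interface extraction --------------------------------------------------

# Trace an ordered simple path through the pixel set `pix` (n x 2 matrix of
# 8-connected pixels, each with <= 2 neighbours), starting at `start` row.
trace_path <- function(pix, start) {
  n <- nrow(pix)
  key <- pix[, 1L] * 1e6 + pix[, 2L]
  used <- rep(FALSE, n)
  ord <- integer(n)
  cur <- start
  for (i in seq_len(n)) {
    ord[i] <- cur
    used[cur] <- TRUE
    dr <- abs(pix[, 1L] - pix[cur, 1L])
    dc <- abs(pix[, 2L] - pix[cur, 2L])
    nxt <- which(!used & dr <= 1L & dc <= 1L)
    if (length(nxt) == 0L) break
    # prefer orthogonal continuation for determinism
    if (length(nxt) > 1L) {
      d <- pmax(dr[nxt], dc[nxt]) + 0.1 * (dr[nxt] + dc[nxt])
      nxt <- nxt[order(d, pix[nxt, 1L], pix[nxt, 2L])]
    }
    cur <- nxt[1L]
  }
  pix[ord[seq_len(i)], , drop = FALSE]
}

# BFS shortest pixel path within mask from `from` (r,c) to `to` (r,c);
# returns the path excluding `from`, or NULL if unreachable.
bfs_path <- function(mask, from, to) {
  nr <- nrow(mask)
  idx <- function(p) (p[2L] - 1L) * nr + p[1L]
  prev <- integer(0)
  visited <- new.env(hash = TRUE)
  assign(as.character(idx(from)), 0L, envir = visited)
  frontier <- list(from)
  parent <- list()
  found <- FALSE
  while (length(frontier) && !found) {
    nextf <- list()
    for (p in frontier) {
      for (k in seq_len(8L)) {
        q <- c(p[1L] + NB8[k, 1L], p[2L] + NB8[k, 2L])
        if (q[1L] < 1L || q[1L] > nr || q[2L] < 1L || q[2L] > ncol(mask)) next
        if (!mask[q[1L], q[2L]]) next
        ky <- as.character(idx(q))
        if (!is.null(visited[[ky]])) next
        visited[[ky]] <- idx(p)
        nextf[[length(nextf) + 1L]] <- q
        if (q[1L] == to[1L] && q[2L] == to[2L]) { found <- TRUE; break }
      }
      if (found) break
    }
    frontier <- nextf
  }
  if (is.null(visited[[as.character(idx(to))]])) return(NULL)
  # backtrack
  path <- list(to)
  cur <- to
  repeat {
    pk <- visited[[as.character(idx(cur))]]
    if (pk == 0L) break
    cur <- c((pk - 1L) %% nr + 1L, (pk - 1L) %/% nr + 1L)
    path[[length(path) + 1L]] <- cur
  }
  do.call(rbind, rev(path))[-1L, , drop = FALSE]
}

#' Extract corner-to-corner interfaces from a skeleton
#'
#' The skeleton is traversed as a graph whose nodes are corners and whose
#' edges are corner-free skeleton paths: skeleton pixels within Chebyshev
#' distance `zone_radius` of a corner form that corner's zone; the remaining
#' pixels split into simple path segments, each connected back to its two
#' delimiting corners through the zones. Each segment becomes one interface
#' record with the ordered pixel path running corner to corner and the two
#' flanking cell labels. Duplicates are removed on the canonical
#' (min corner, max corner, cell pair) key. Paths with an end attached to no
#' corner are flagged `dangling`; closed loops without corners are flagged
#' `loop`; paths shorter than `min_length` pixels are flagged `degenerate`;
#' interfaces of border-flagged cells are flagged `border`. Only unflagged
#' interfaces are measured downstream (flagged ones are retained for the log).
#'
#' @param skeleton a [skeleton_map].
#' @param corners corner data frame ([detect_corners()] / [adjust_corners()]).
#' @param labels matching `cell_label_map`.
#' @param zone_radius corner-zone radius in pixels.
#' @param min_length minimum path pixel count for a measurable interface.
#' @param exclude_border drop interfaces touching border-flagged cells.
#' @return list of interface records, each a list with `id`, `corner_a`,
#'   `corner_b`, `path` (n x 2 matrix), `cell_pair`, `junction_class`,
#'   `flag` (`""` when measurable).
#' @export
extract_interfaces <- function(skeleton, corners, labels,
                               zone_radius = 3L, min_length = 5L,
                               exclude_border = TRUE) {
  m <- skeleton$pixels
  nr <- nrow(m); nc <- ncol(m)
  zone_radius <- as.integer(zone_radius)
  cz <- matrix(0L, nr, nc)          # corner id owning each zone pixel
  if (nrow(corners)) {
    # nearest corner within zone_radius (Chebyshev) of each skeleton pixel
    for (i in seq_len(nrow(corners))) {
      r <- corners$row[i]; c <- corners$col[i]
      rs <- max(1L, r - zone_radius):min(nr, r + zone_radius)
      cs <- max(1L, c - zone_radius):min(nc, c + zone_radius)
      blk <- cz[rs, cs]
      sel <- m[rs, cs] == 1L & blk == 0L
      blk[sel] <- corners$id[i]
      cz[rs, cs] <- blk
    }
  }
  # the thinned branch point can sit a few pixels off the snapped corner
  # position; absorb true branch pixels (and their skeleton neighbours)
  # into the nearest corner's zone so every arm separates cleanly
  if (nrow(corners)) {
    bp <- which(m == 1L & crossing_number(m) >= 3, arr.ind = TRUE)
    reach <- 2L * zone_radius + 2L
    for (i in seq_len(nrow(bp))) {
      dch <- pmax(abs(corners$row - bp[i, 1L]), abs(corners$col - bp[i, 2L]))
      k <- which.min(dch)
      if (dch[k] <= reach) {
        rs <- max(1L, bp[i, 1L] - 1L):min(nr, bp[i, 1L] + 1L)
        cs <- max(1L, bp[i, 2L] - 1L):min(nc, bp[i, 2L] + 1L)
        blk <- cz[rs, cs]
        sel <- m[rs, cs] == 1L & blk == 0L
        blk[sel] <- corners$id[k]
        cz[rs, cs] <- blk
      }
    }
  }
  free <- (m == 1L) & (cz == 0L)
  comp <- label8(free + 0L)
  ncomp <- max(comp)
  records <- list()
  rid <- 0L
  for (g in seq_len(ncomp)) {
    pix <- which(comp == g, arr.ind = TRUE)
    colnames(pix) <- NULL
    bcount <- integer(nrow(pix))
    for (i in seq_len(nrow(pix))) {
      dr <- abs(pix[, 1L] - pix[i, 1L]); dc <- abs(pix[, 2L] - pix[i, 2L])
      bcount[i] <- sum(dr <= 1L & dc <= 1L) - 1L
    }
    flag <- ""
    if (any(bcount > 2L)) flag <- "branched"
    ends <- which(bcount <= 1L)
    if (length(ends) == 0L) {          # loop without corners
      rid <- rid + 1L
      records[[rid]] <- list(id = rid, corner_a = NA_integer_,
                             corner_b = NA_integer_, path = pix,
                             cell_pair = flank_cells(pix, labels$labels),
                             junction_class = "untyped", flag = "loop")
      next
    }
    ends <- ends[order(pix[ends, 1L], pix[ends, 2L])]
    path <- trace_path(pix, ends[1L])
    # a path sneaking past a corner just outside its zone is really two
    # interfaces whose arms touch: split it at every mid-path close
    # approach to a corner position
    segments <- list()
    forced <- list()
    if (nrow(corners)) {
      dch <- matrix(Inf, nrow(path), 1L)
      nearest <- integer(nrow(path))
      for (i in seq_len(nrow(path))) {
        dd <- pmax(abs(corners$row - path[i, 1L]),
                   abs(corners$col - path[i, 2L]))
        dch[i] <- min(dd)
        nearest[i] <- corners$id[which.min(dd)]
      }
      close <- which(dch <= zone_radius + 1L)
      close <- close[close > 3L & close < nrow(path) - 3L]
      if (length(close)) {
        runs <- split(close, cumsum(c(1L, diff(close) > 1L)))
        cuts <- vapply(runs, function(ix) ix[which.min(dch[ix])], integer(1))
        bounds <- c(1L, cuts, nrow(path))
        for (s in seq_len(length(cuts) + 1L)) {
          lo <- bounds[s]; hi <- bounds[s + 1L]
          segments[[s]] <- path[lo:hi, , drop = FALSE]
          forced[[s]] <- c(if (s > 1L) nearest[cuts[s - 1L]] else NA_integer_,
                           if (s <= length(cuts)) nearest[cuts[s]]
                           else NA_integer_)
        }
      }
    }
    if (!length(segments)) {
      segments <- list(path)
      forced <- list(c(NA_integer_, NA_integer_))
    }
    for (s in seq_along(segments)) {
      res <- build_record(segments[[s]], forced[[s]], cz, m, corners, labels,
                          min_length, exclude_border, flag, nr, nc)
      rid <- rid + 1L
      res$id <- rid
      records[[rid]] <- res
    }
  }
  dedupe_interfaces(records)
}

# Attach a traced path segment to its delimiting corners (via zone
# adjacency, or a corner id forced by a mid-path split), extend it through
# the zones to the corner positions, and assemble the interface record.
build_record <- function(path, forced_att, cz, m, corners, labels,
                         min_length, exclude_border, flag, nr, nc) {
  att <- forced_att
  endpts <- list(path[1L, ], path[nrow(path), ])
  for (e in 1:2) {
    if (!is.na(att[e])) next
    p <- endpts[[e]]
    rs <- max(1L, p[1L] - 1L):min(nr, p[1L] + 1L)
    cs <- max(1L, p[2L] - 1L):min(nc, p[2L] + 1L)
    ids <- cz[rs, cs]
    ids <- ids[ids > 0L]
    # a very short segment can touch both corners at each end; prefer a
    # corner not already claimed by the other end
    other <- att[-e]
    if (length(setdiff(ids, other))) ids <- setdiff(ids, other)
    if (length(ids)) {
      tab <- sort(table(ids), decreasing = TRUE)
      att[e] <- as.integer(names(tab)[1L])
    }
  }
  if (anyNA(att)) {
    return(list(id = NA_integer_, corner_a = att[1L], corner_b = att[2L],
                path = path, cell_pair = flank_cells(path, labels$labels),
                junction_class = "untyped", flag = "dangling"))
  }
  full <- path
  for (e in 1:2) {
    ci <- att[e]
    cpos <- c(corners$row[corners$id == ci], corners$col[corners$id == ci])
    endp <- if (e == 1L) full[1L, ] else full[nrow(full), ]
    if (all(endp == cpos)) next
    near_corner <- m == 1L & abs(row(m) - cpos[1L]) <= 5L &
      abs(col(m) - cpos[2L]) <= 5L
    zone_mask <- (cz == ci) | near_corner |
      (m == 1L & abs(row(m) - endp[1L]) <= 1L & abs(col(m) - endp[2L]) <= 1L)
    seg <- bfs_path(zone_mask, endp, cpos)
    if (is.null(seg)) next
    if (e == 1L) full <- rbind(seg[rev(seq_len(nrow(seg))), , drop = FALSE],
                               full)
    else full <- rbind(full, seg)
  }
  ca <- min(att); cb <- max(att)
  if (att[1L] != ca) full <- full[rev(seq_len(nrow(full))), , drop = FALSE]
  cp <- flank_cells(full, labels$labels)
  if (flag == "" && nrow(full) < min_length) flag <- "degenerate"
  if (flag == "" && length(cp) < 2L) flag <- "no_cell_pair"
  if (flag == "" && exclude_border && any(labels$border[cp]))
    flag <- "border"
  list(id = NA_integer_, corner_a = ca, corner_b = cb, path = full,
       cell_pair = cp, junction_class = "untyped", flag = flag)
}

# The two flanking cell labels along a path: the two nonzero labels with the
# strongest pixel support within Chebyshev distance 1 of path pixels.
flank_cells <- function(path, labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  counts <- integer(0)
  tally <- new.env(hash = TRUE)
  for (i in seq_len(nrow(path))) {
    rs <- max(1L, path[i, 1L] - 1L):min(nr, path[i, 1L] + 1L)
    cs <- max(1L, path[i, 2L] - 1L):min(nc, path[i, 2L] + 1L)
    v <- labels[rs, cs]
    for (lb in unique(v[v > 0L])) {
      ky <- as.character(lb)
      tally[[ky]] <- (if (is.null(tally[[ky]])) 0L else tally[[ky]]) + 1L
    }
  }
  labs <- as.integer(ls(tally))
  if (length(labs) == 0L) return(integer(0))
  cnt <- vapply(as.character(labs), function(k) tally[[k]], integer(1))
  labs <- labs[order(-cnt, labs)]
  sort(labs[seq_len(min(2L, length(labs)))])
}

# Keep one record per canonical (corner_a, corner_b, cell_pair) key;
# measuring a junction from either flanking cell yields the same record.
dedupe_interfaces <- function(records) {
  if (!length(records)) return(records)
  keys <- vapply(records, function(r) {
    paste(r$corner_a, r$corner_b, paste(r$cell_pair, collapse = "-"),
          sep = "|")
  }, character(1))
  keep <- !duplicated(keys) | grepl("NA", keys)
  records <- records[keep]
  for (i in seq_along(records)) records[[i]]$id <- i
  records
}

#' Classify junctions by expression status of their flanking cells
#'
#' A cell is "expressing" when at least `min_fraction` of its pixels are
#' positive in the expression mask (the boundary rule is inclusive:
#' coverage exactly at `min_fraction` counts as expressing). Junctions are
#' labelled `ee` (both cells expressing), `en` (exactly one) or `control`
#' (neither).
#'
#' @param interfaces list of interface records.
#' @param labels `cell_label_map`.
#' @param expression_mask binary matrix, same shape as the label map.
#' @param min_fraction fraction in `[0, 1]`.
#' @return the interface list with `junction_class` set.
#' @export
classify_junctions <- function(interfaces, labels, expression_mask,
                               min_fraction = 0.5) {
  if (!identical(dim(labels$labels), dim(expression_mask)))
    stop("expression mask shape differs from label map")
  n <- labels$n_cells
  lab <- labels$labels
  tot <- tabulate(lab[lab > 0L], nbins = n)
  pos <- tabulate(lab[lab > 0L & expression_mask > 0], nbins = n)
  expressing <- (pos / pmax(tot, 1L)) >= min_fraction
  for (i in seq_along(interfaces)) {
    cp <- interfaces[[i]]$cell_pair
    if (length(cp) < 2L) next
    ne <- sum(expressing[cp])
    interfaces[[i]]$junction_class <-
      c("control", "en", "ee")[ne + 1L]
  }
  interfaces
}
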