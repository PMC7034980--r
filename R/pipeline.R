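#' Measure every cell-cell junction in a fluorescence image
#'
#' The main entry point: runs the full semi-automated measurement pipeline
#' on a junction-marker image and returns one measurement row per
#' deduplicated junction. Stages: boundary detection ([detect_edges()]),
#' thinning to a one-pixel skeleton ([skeletonize()]), scripted manual
#' edits ([apply_edits()]), intensity-ridge refinement
#' ([refine_skeleton()]), cell labelling ([label_cells()]), tricellular
#' corner detection ([detect_corners()] / [adjust_corners()]), interface
#' extraction with deduplication and border exclusion
#' ([extract_interfaces()]), optional expression classification
#' ([classify_junctions()]), then per-interface band dilation and
#' measurement ([dilate_interface()], [measure_primary()],
#' [derive_secondary()], and [measure_second_marker()] for a second
#' channel).
#'
#' Any stage can be short-circuited with precomputed inputs: supply
#' `skeleton` to skip automatic detection, or `interfaces` (e.g. from
#' [truth_interfaces()]) to skip topology extraction entirely — the
#' scripted equivalents of interactive correction.
#'
#' @param image junction-marker [raster_image] (or path loadable by
#'   [load_image()]).
#' @param threshold marker-1 intensity threshold (strict `>`); the minimal
#'   threshold that removes background without clipping junction staining.
#' @param dilation band half-width in pixels, 1..9.
#' @param marker2,threshold2 optional co-registered second marker and its
#'   threshold; measured inside marker 1's bands.
#' @param expression_mask optional binary mask of transfected/expressing
#'   cells; enables ee/en/control classification.
#' @param skeleton optional precomputed [skeleton_map].
#' @param interfaces optional precomputed interface record list.
#' @param edits optional [edit_script()] applied after detection.
#' @param corner_additions,corner_removals manual corner adjustments,
#'   passed to [adjust_corners()].
#' @param refine snap the skeleton onto intensity ridges before topology.
#' @param blur_radius,local_window,binarize_threshold [detect_edges()]
#'   settings.
#' @param spur_prune spur-pruning length for [skeletonize()].
#' @param search_radius [refine_skeleton()] window half-width.
#' @param corner_radius [detect_corners()] radius.
#' @param min_interface minimum measurable path length, px.
#' @param border_margin,exclude_border border-cell handling
#'   ([label_cells()], [extract_interfaces()]).
#' @param min_fraction expressing-cell pixel fraction
#'   ([classify_junctions()]).
#' @param gap_tolerance covered-run gap tolerance ([covered_runs()]).
#' @param cluster_denominator see [derive_secondary()].
#' @param image_id identifier written into the results table.
#' @param psnr_reference optional clean reference [raster_image]; when
#'   given, the PSNR of `image` against it is computed and a warning flag
#'   is logged below 22 dB (automatic skeletons become unreliable).
#' @return an object of class `junction_map`; see [print.junction_map()],
#'   [summary.junction_map()], [as.data.frame.junction_map()],
#'   [plot.junction_map()], [write_junction_csv()].
#' @export
junction_map <- function(image, threshold, dilation = 2L,
                         marker2 = NULL, threshold2 = NULL,
                         expression_mask = NULL,
                         skeleton = NULL, interfaces = NULL, edits = NULL,
                         corner_additions = NULL, corner_removals = NULL,
                         refine = TRUE, blur_radius = 2, local_window = 21L,
                         binarize_threshold = 1.3, spur_prune = 5L,
                         search_radius = 2L, corner_radius = 2L,
                         min_interface = 5L, border_margin = 2L,
                         exclude_border = TRUE, min_fraction = 0.5,
                         gap_tolerance = 0L,
                         cluster_denominator = "marker_area",
                         image_id = "image", psnr_reference = NULL) {
  if (is.character(image)) image <- load_image(image)
  if (is.character(marker2)) marker2 <- load_image(marker2)
  if (!is.null(marker2) && is.null(threshold2))
    stop("'threshold2' is required when 'marker2' is given")
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  if (!is.null(psnr_reference)) {
    psnr <- compute_psnr(psnr_reference, image)
    note("psnr: %.2f dB%s", psnr,
         if (is.finite(psnr) && psnr < 22)
           " [below the 22 dB automatic-skeleton guideline]" else "")
  } else psnr <- NA_real_

  corners <- NULL
  labels <- NULL
  if (is.null(interfaces)) {
    if (is.null(skeleton)) {
      edgemask <- detect_edges(image, blur_radius = blur_radius,
                               local_window = local_window,
                               binarize_threshold = binarize_threshold)
      skeleton <- skeletonize(edgemask, prune_len = spur_prune)
      note("auto skeleton: %d boundary pixels", sum(skeleton$pixels))
    }
    if (!is.null(edits)) {
      skeleton <- apply_edits(skeleton, edits)
      note("edits applied: %d", length(edits))
    }
    if (isTRUE(refine)) {
      skeleton <- refine_skeleton(skeleton, image, search_radius)
    }
    labels <- label_cells(skeleton, border_margin = border_margin)
    note("cells: %d (%d border-flagged)", labels$n_cells,
         sum(labels$border))
    corners <- detect_corners(skeleton, labels, radius = corner_radius)
    corners <- refine_corner_positions(corners, skeleton, image, threshold)
    if (!is.null(corner_additions) || !is.null(corner_removals))
      corners <- adjust_corners(corners, skeleton, labels,
                                additions = corner_additions,
                                removals = corner_removals,
                                radius = corner_radius)
    note("corners: %d", nrow(corners))
    interfaces <- extract_interfaces(skeleton, corners, labels,
                                     zone_radius = corner_radius + 1L,
                                     min_length = min_interface,
                                     exclude_border = exclude_border)
  }
  if (!is.null(expression_mask) && !is.null(labels))
    interfaces <- classify_junctions(interfaces, labels, expression_mask,
                                     min_fraction)

  rows <- list()
  for (rec in interfaces) {
    if (!identical(rec$flag, "")) {
      note("interface %d excluded: %s", rec$id, rec$flag)
      next
    }
    band <- dilate_interface(rec, dilation, dim(image))
    p <- measure_primary(rec, band, image, threshold, gap_tolerance)
    s <- derive_secondary(p, cluster_denominator)
    row <- c(list(image_id = image_id, interface_id = rec$id,
                  corner_a = rec$corner_a, corner_b = rec$corner_b,
                  cell_a = rec$cell_pair[1L], cell_b = rec$cell_pair[2L],
                  junction_class = rec$junction_class),
             stats::setNames(unclass(p), paste0("m1_", names(p))),
             stats::setNames(unclass(s), paste0("m1_", names(s))))
    if (!is.null(marker2)) {
      m2 <- measure_second_marker(rec, band, marker2, threshold2,
                                  gap_tolerance, cluster_denominator)
      row <- c(row,
               stats::setNames(unclass(m2$primary),
                               paste0("m2_", names(m2$primary))),
               stats::setNames(unclass(m2$secondary),
                               paste0("m2_", names(m2$secondary))))
    }
    rows[[length(rows) + 1L]] <- row
  }
  table <- if (length(rows))
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  else NULL
  if (!is.null(table)) {
    table$dilation <- as.integer(dilation)
    table$threshold <- threshold
    if (!is.null(marker2)) table$threshold2 <- threshold2
    rownames(table) <- NULL
  }
  structure(list(table = table, interfaces = interfaces, corners = corners,
                 skeleton = skeleton, labels = labels, image = image,
                 psnr = psnr, log = log,
                 config = list(threshold = threshold, dilation = dilation,
                               threshold2 = threshold2,
                               corner_radius = corner_radius,
                               spur_prune = spur_prune,
                               min_interface = min_interface,
                               exclude_border = exclude_border,
                               min_fraction = min_fraction,
                               gap_tolerance = gap_tolerance,
                               cluster_denominator = cluster_denominator,
                               image_id = image_id)),
            class = "junction_map")
}

#' @export
print.junction_map <- function(x, ...) {
  n <- if (is.null(x$table)) 0L else nrow(x$table)
  cat(sprintf("<junction_map> %d measured junction(s) (threshold %g, dilation %d)\n",
              n, x$config$threshold, x$config$dilation))
  excl <- grep("excluded", x$log, value = TRUE)
  if (length(excl)) cat(sprintf("  %d interface(s) excluded\n", length(excl)))
  if (n) {
    cat("  median coverage index:",
        sprintf("%.1f%%", stats::median(x$table$m1_coverage_index)), "\n")
    cat("  median interface linearity:",
        sprintf("%.3f", stats::median(x$table$m1_interface_linearity_index)),
        "\n")
  }
  invisible(x)
}

#' Summary of a junction_map analysis
#'
#' Per-parameter median, interquartile range and n over the measured
#' junctions, split by junction class when classes are present.
#'
#' @param object a `junction_map`.
#' @param ... unused.
#' @export
summary.junction_map <- function(object, ...) {
  tab <- object$table
  if (is.null(tab) || !nrow(tab)) {
    cat("no measured junctions\n")
    return(invisible(NULL))
  }
  params <- grep("^m[12]_", names(tab), value = TRUE)
  classes <- unique(tab$junction_class)
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- tab[tab$junction_class == cl, params, drop = FALSE]
    data.frame(junction_class = cl, parameter = params,
               n = colSums(!is.na(sub)),
               median = apply(sub, 2L, stats::median, na.rm = TRUE),
               q25 = apply(sub, 2L, stats::quantile, 0.25, na.rm = TRUE),
               q75 = apply(sub, 2L, stats::quantile, 0.75, na.rm = TRUE),
               row.names = NULL)
  }))
  class(out) <- c("summary.junction_map", "data.frame")
  out
}

#' @export
print.summary.junction_map <- function(x, ...) {
  y <- x
  class(y) <- "data.frame"
  y$median <- signif(y$median, 4)
  y$q25 <- signif(y$q25, 4)
  y$q75 <- signif(y$q75, 4)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Results table of a junction_map analysis
#'
#' @param x a `junction_map`.
#' @param row.names,optional passed through.
#' @param units `"px"` (native) or `"um"`; with `"um"`, length columns are
#'   multiplied by `pixel_size` and area columns by `pixel_size^2` (report
#'   convenience only — core computation is always in pixels).
#' @param pixel_size micrometres per pixel, required for `units = "um"`.
#' @param ... unused.
#' @export
as.data.frame.junction_map <- function(x, row.names = NULL, optional = FALSE,
                                       units = c("px", "um"),
                                       pixel_size = NULL, ...) {
  units <- match.arg(units)
  tab <- x$table
  if (is.null(tab)) return(data.frame())
  if (units == "um") {
    if (is.null(pixel_size)) stop("'pixel_size' required for units = 'um'")
    lencols <- grep("contour|length", names(tab), value = TRUE)
    areacols <- grep("_area$", names(tab), value = TRUE)
    for (cl in lencols) tab[[cl]] <- tab[[cl]] * pixel_size
    for (cl in areacols) tab[[cl]] <- tab[[cl]] * pixel_size^2
  }
  tab
}

#' Write the per-junction results table as CSV
#'
#' CSV (not a spreadsheet binary) is the canonical output: lossless,
#' diffable and toolchain-neutral. Identical configuration and seed produce
#' a byte-identical file.
#'
#' @param x a `junction_map` or a plain results data frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_junction_csv <- function(x, path) {
  tab <- if (inherits(x, "junction_map")) x$table else x
  utils::write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Overlay plot of skeleton, corners and measured interfaces
#'
#' Renders the marker image with the skeleton and numbered corners
#' overlaid — the visual QC view of the segmentation.
#'
#' @param x a `junction_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.junction_map <- function(x, ...) {
  img <- x$image
  nr <- nrow(img); nc <- ncol(img)
  graphics::image(t(unclass(img))[, nr:1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nr / nc, ...)
  if (!is.null(x$skeleton)) {
    pts <- which(x$skeleton$pixels == 1L, arr.ind = TRUE)
    graphics::points((pts[, 2L] - 1) / (nc - 1), (nr - pts[, 1L]) / (nr - 1),
                     pch = ".", col = "red")
  }
  if (!is.null(x$corners) && nrow(x$corners)) {
    graphics::points((x$corners$col - 1) / (nc - 1),
                     (nr - x$corners$row) / (nr - 1),
                     pch = 0, col = "yellow", cex = 1.2)
    graphics::text((x$corners$col - 1) / (nc - 1),
                   (nr - x$corners$row) / (nr - 1),
                   labels = x$corners$id, col = "yellow", pos = 3, cex = 0.6)
  }
  invisible(x)
}
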