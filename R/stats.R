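#' Compare a junction parameter between groups
#'
#' Per-junction data are typically non-parametric, so two groups are
#' compared with the two-sided Mann-Whitney U test; three or more groups
#' with one-way ANOVA followed by the Games-Howell post-hoc test, which
#' tolerates unequal group sizes and variances. Normality diagnostics
#' (Shapiro-Wilk and Lilliefors/Kolmogorov-Smirnov) are reported per group
#' but drive no automatic decision; the conventional significance threshold
#' is p < 0.05 and is reported, never hard-coded into a conclusion.
#'
#' @param table a `junction_map` object or its results data frame.
#' @param parameter column name to compare (e.g. `"m1_coverage_index"`).
#' @param grouping column defining the groups (default the junction class).
#' @return object of class `group_comparison`: list with `method`,
#'   `p_value` (global), `pairwise` (data frame; for 2 groups the single
#'   Mann-Whitney row), `normality`, `group_stats`.
#' @export
compare_groups <- function(table, parameter,
                           grouping = "junction_class") {
  if (inherits(table, "junction_map")) table <- table$table
  if (!parameter %in% names(table)) stop("unknown parameter: ", parameter)
  if (!grouping %in% names(table)) stop("unknown grouping: ", grouping)
  vals <- table[[parameter]]
  grp <- as.character(table[[grouping]])
  ok <- !is.na(vals) & !is.na(grp)
  vals <- vals[ok]; grp <- grp[ok]
  groups <- split(vals, grp)
  if (length(groups) < 2L)
    stop("need >= 2 groups with data in '", grouping, "'")
  small <- names(groups)[vapply(groups, length, integer(1)) < 3L]
  if (length(small))
    stop("group(s) too small (< 3 observations): ",
         paste(small, collapse = ", "))
  gs <- data.frame(group = names(groups),
                   n = vapply(groups, length, integer(1)),
                   median = vapply(groups, stats::median, numeric(1)),
                   mean = vapply(groups, mean, numeric(1)),
                   sd = vapply(groups, stats::sd, numeric(1)),
                   row.names = NULL)
  norm <- do.call(rbind, lapply(names(groups), function(g) {
    v <- groups[[g]]
    sw <- if (length(v) >= 3L && length(v) <= 5000L &&
              stats::sd(v) > 0)
      tryCatch(stats::shapiro.test(v)$p.value, error = function(e) NA_real_)
    else NA_real_
    ks <- if (length(v) >= 5L && stats::sd(v) > 0)
      tryCatch(nortest::lillie.test(v)$p.value, error = function(e) NA_real_)
    else NA_real_
    data.frame(group = g, shapiro_p = sw, ks_lilliefors_p = ks)
  }))
  if (length(groups) == 2L) {
    wt <- stats::wilcox.test(groups[[1L]], groups[[2L]], exact = FALSE,
                             correct = TRUE)
    pw_p <- wt$p.value
    if (is.nan(pw_p)) pw_p <- 1   # all observations tied across groups
    pairwise <- data.frame(group1 = names(groups)[1L],
                           group2 = names(groups)[2L],
                           statistic = unname(wt$statistic),
                           p = pw_p)
    out <- list(method = "Mann-Whitney U", p_value = pw_p,
                pairwise = pairwise, normality = norm, group_stats = gs,
                parameter = parameter)
  } else {
    an <- stats::oneway.test(vals ~ factor(grp), var.equal = TRUE)
    pairwise <- games_howell(vals, grp)
    out <- list(method = "one-way ANOVA + Games-Howell",
                p_value = an$p.value, pairwise = pairwise,
                normality = norm, group_stats = gs, parameter = parameter)
  }
  class(out) <- "group_comparison"
  out
}

#' Games-Howell post-hoc pairwise comparisons
#'
#' Welch-type pairwise statistic with a studentized-range reference
#' distribution: for groups i and j,
#' `t = |mi - mj| / sqrt(si^2/ni + sj^2/nj)`, Welch-Satterthwaite degrees
#' of freedom, and `p = ptukey(t * sqrt(2), k, df, lower.tail = FALSE)`
#' with `k` the number of groups. Designed for unequal group sizes and
#' variances.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation (>= 3 groups).
#' @return data frame with columns `group1`, `group2`, `diff`, `t`, `df`,
#'   `p`.
#' @export
games_howell <- function(values, groups) {
  g <- split(values, as.character(groups))
  k <- length(g)
  if (k < 3L) stop("Games-Howell needs >= 3 groups")
  nm <- names(g)
  n <- vapply(g, length, integer(1))
  m <- vapply(g, mean, numeric(1))
  v <- vapply(g, stats::var, numeric(1))
  out <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1L) +
                     (v[j] / n[j])^2 / (n[j] - 1L))
    p <- if (se2 == 0) 1 else
      stats::ptukey(tstat * sqrt(2), nmeans = k, df = df,
                    lower.tail = FALSE)
    out[[length(out) + 1L]] <-
      data.frame(group1 = nm[i], group2 = nm[j], diff = m[j] - m[i],
                 t = tstat, df = df, p = p)
  }
  do.call(rbind, out)
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s on '%s': global p = %s\n", x$method, x$parameter,
              format.pval(x$p_value, digits = 3)))
  pw <- x$pairwise
  pw$p <- format.pval(pw$p, digits = 3)
  print(pw, row.names = FALSE)
  invisible(x)
}

#' Control-normalized phenotype fingerprint
#'
#' For each treated group and each parameter, the treated median is
#' expressed as a percentage of the control median (controls arbitrarily
#' set to 100), with the Mann-Whitney significance flag of the
#' treated-vs-control comparison. Medians (not means) are used because
#' per-junction data are non-parametric. The resulting profile of
#' normalized deviations is the phenotype's fingerprint.
#'
#' @param table `junction_map` object or results data frame.
#' @param control_group label of the control group in `grouping`.
#' @param parameters character vector of parameter columns; default the
#'   six marker-1 secondary parameters plus marker intensity.
#' @param grouping grouping column.
#' @param alpha significance threshold reported alongside each entry.
#' @return object of class `junction_fingerprint` (a data frame with
#'   columns `group`, `parameter`, `normalized`, `p`, `significant`).
#' @export
normalize_profile <- function(table, control_group,
                              parameters = NULL,
                              grouping = "junction_class",
                              alpha = 0.05) {
  if (inherits(table, "junction_map")) table <- table$table
  if (is.null(parameters))
    parameters <- intersect(
      c("m1_interface_linearity_index", "m1_coverage_index",
        "m1_interface_occupancy", "m1_intensity_per_interface_area",
        "m1_cluster_density", "m1_marker_intensity"),
      names(table))
  grp <- as.character(table[[grouping]])
  if (!control_group %in% grp)
    stop("control group '", control_group, "' absent from '", grouping, "'")
  treated <- setdiff(unique(grp), control_group)
  rows <- list()
  for (param in parameters) {
    ctrl <- table[[param]][grp == control_group]
    ctrl <- ctrl[!is.na(ctrl)]
    cmed <- stats::median(ctrl)
    for (tg in treated) {
      tv <- table[[param]][grp == tg]
      tv <- tv[!is.na(tv)]
      if (cmed == 0 || !length(tv)) {
        rows[[length(rows) + 1L]] <-
          data.frame(group = tg, parameter = param, normalized = NA_real_,
                     p = NA_real_, significant = NA,
                     note = "non-normalizable (zero control median)")
        next
      }
      p <- if (length(tv) >= 3L && length(ctrl) >= 3L)
        stats::wilcox.test(tv, ctrl, exact = FALSE)$p.value else NA_real_
      if (is.nan(p)) p <- 1   # all observations tied across groups
      rows[[length(rows) + 1L]] <-
        data.frame(group = tg, parameter = param,
                   normalized = 100 * stats::median(tv) / cmed,
                   p = p, significant = !is.na(p) & p < alpha, note = "")
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "control_group") <- control_group
  attr(out, "center") <- "median"
  class(out) <- c("junction_fingerprint", "data.frame")
  out
}

#' @export
print.junction_fingerprint <- function(x, ...) {
  cat(sprintf("junction fingerprint (control '%s' = 100, center = %s)\n",
              attr(x, "control_group"), attr(x, "center")))
  y <- x
  class(y) <- "data.frame"
  y$normalized <- round(y$normalized, 1)
  y$p <- format.pval(y$p, digits = 3)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Bubble-chart rendering of a fingerprint
#'
#' Circles of area proportional to the normalized value, one row per
#' treated group and one column per parameter; non-significant entries
#' are drawn hollow.
#'
#' @param x a `junction_fingerprint`.
#' @param ... unused.
#' @export
plot.junction_fingerprint <- function(x, ...) {
  params <- unique(x$parameter)
  grps <- unique(x$group)
  xi <- match(x$parameter, params)
  yi <- match(x$group, grps)
  graphics::plot(NA, xlim = c(0.5, length(params) + 0.5),
                 ylim = c(0.5, length(grps) + 1.5), axes = FALSE,
                 xlab = "", ylab = "", ...)
  graphics::axis(1, at = seq_along(params),
                 labels = sub("^m1_", "", params), las = 2, cex.axis = 0.7)
  graphics::axis(2, at = seq_along(grps), labels = grps, las = 1)
  # control reference row of size-100 circles
  graphics::symbols(seq_along(params), rep(length(grps) + 1, length(params)),
                    circles = rep(0.2, length(params)), inches = FALSE,
                    add = TRUE, fg = "orange", bg = "orange")
  r <- 0.2 * sqrt(pmax(x$normalized, 0) / 100)
  filled <- ifelse(is.na(x$significant) | !x$significant, NA, "steelblue")
  graphics::symbols(xi, yi, circles = pmax(r, 0.02), inches = FALSE,
                    add = TRUE, fg = "steelblue", bg = filled)
  invisible(x)
}
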