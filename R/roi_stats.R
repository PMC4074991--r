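# ROI-level aggregation and group statistics: normalized volume of
# activation, Kruskal-Wallis / Mann-Whitney genotype comparisons, Fisher's
# protected LSD volume contrasts, and ROI time-course analysis.

#' Per-region volume of activation
#'
#' Counts significant voxels per atlas region and normalizes each count to
#' that subject's own region size:
#' normalized VOA = activated voxels x 100 / total voxels in the ROI.
#' Regions with zero voxels in the atlas are excluded with a warning.
#'
#' @param map a [activation_map()] result resampled into atlas space (or a
#'   3D logical significance array on the atlas grid).
#' @param atlas a [segmented_atlas()] on the same grid.
#' @return data.frame with columns `id`, `name`, `activated_voxels`,
#'   `total_voxels`, `normalized_voa` (percent, in `[0, 100]`).
#' @export
volume_of_activation <- function(map, atlas) {
  sig <- if (inherits(map, "voxel_activation_map")) map$significant else map
  sig <- array(as.logical(sig), dim = dim(sig))
  if (!identical(dim(sig), dim(atlas$labels)))
    stop("map and atlas must share a grid")
  ids <- sort(atlas$regions$id)
  nb <- max(ids)
  total <- tabulate(atlas$labels[atlas$labels > 0L], nbins = nb)[ids]
  act <- tabulate(atlas$labels[sig & atlas$labels > 0L], nbins = nb)[ids]
  empty <- total == 0L
  if (any(empty)) {
    warning("excluding regions with zero voxels: ",
            paste(ids[empty], collapse = ", "))
  }
  out <- data.frame(id = ids,
                    name = atlas$regions$name[match(ids, atlas$regions$id)],
                    activated_voxels = act, total_voxels = total,
                    normalized_voa = ifelse(total > 0, 100 * act / total, NA_real_),
                    stringsAsFactors = FALSE)
  out[!empty, , drop = FALSE]
}

# Mann-Whitney U test: exact null distribution when the combined sample size
# is <= 12 and there are no ties; normal approximation with continuity and
# tie correction otherwise. Two-sided throughout.
mann_whitney_u <- function(x, y) {
  if (length(unique(c(x, y))) == 1L)
    return(list(U = length(x) * length(y) / 2, p = 1))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y) <= 12L) && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value)
}

# Kruskal-Wallis omnibus, guarding the all-tied degenerate case
kruskal_omnibus <- function(values, groups) {
  if (length(unique(values)) == 1L) {
    warning("all observations tied; omnibus p set to 1")
    return(list(H = 0, p = 1))
  }
  ht <- stats::kruskal.test(values, factor(groups))
  list(H = unname(ht$statistic), p = ht$p.value)
}

#' Genotype group comparison of normalized volumes of activation
#'
#' For every region: non-parametric Kruskal-Wallis omnibus across the
#' genotype groups on normalized VOA, followed by pairwise two-sided
#' Mann-Whitney U tests. Per group, the median, maximum and minimum
#' normalized VOA are reported, and rows are rank-ordered by omnibus p-value
#' (ties broken by region id), mirroring a volume-of-activation table.
#'
#' @param tables list of per-subject [volume_of_activation()] data.frames.
#' @param groups character/factor of group labels, one per subject. Group
#'   level order is taken from the factor levels (or first appearance).
#' @return data.frame with one row per region: `id`, `name`, then per group
#'   `<g>_median`, `<g>_max`, `<g>_min`, then `p_value` (omnibus) and
#'   pairwise columns `p_<g1>_vs_<g2>`.
#' @export
group_compare <- function(tables, groups) {
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (length(tables) != length(groups))
    stop("one group label per subject table required")
  lv <- levels(groups)
  if (length(lv) < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 subjects each")
  ids <- tables[[1]]$id
  voa <- vapply(tables, function(tb) tb$normalized_voa[match(ids, tb$id)],
                numeric(length(ids)))
  voa <- matrix(voa, nrow = length(ids))
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(seq_along(ids), function(r) {
    v <- voa[r, ]
    row <- list(id = ids[r], name = tables[[1]]$name[r])
    for (g in lv) {
      vg <- v[groups == g]
      row[[paste0(g, "_median")]] <- stats::median(vg)
      row[[paste0(g, "_max")]] <- max(vg)
      row[[paste0(g, "_min")]] <- min(vg)
    }
    omni <- withCallingHandlers(kruskal_omnibus(v, groups),
                                warning = function(w) invokeRestart("muffleWarning"))
    row$p_value <- omni$p
    for (pr in pairs) {
      mw <- mann_whitney_u(v[groups == pr[1]], v[groups == pr[2]])
      row[[paste0("p_", pr[1], "_vs_", pr[2])]] <- mw$p
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, out$id), , drop = FALSE]
}

# Fisher's LSD pairwise t contrast from a one-way ANOVA fit:
# t = (m_i - m_j) / sqrt(MSE (1/n_i + 1/n_j)), df = N - k, two-sided.
fisher_lsd <- function(values, groups) {
  groups <- factor(groups)
  fit <- stats::aov(values ~ groups)
  an <- stats::anova(fit)
  mse <- an["Residuals", "Mean Sq"]
  dfe <- an["Residuals", "Df"]
  m <- tapply(values, groups, mean)
  n <- tapply(values, groups, length)
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    tval <- (m[pr[1]] - m[pr[2]]) / sqrt(mse * (1 / n[pr[1]] + 1 / n[pr[2]]))
    data.frame(contrast = paste(pr[1], "vs", pr[2]),
               t = unname(tval), df = dfe,
               p = unname(2 * stats::pt(-abs(tval), dfe)),
               stringsAsFactors = FALSE)
  })
  list(omnibus_F = an[1, "F value"], omnibus_p = an[1, "Pr(>F)"],
       pairwise = do.call(rbind, res))
}

#' Group comparison of regional brain volumes
#'
#' For every region: per-group mean volume (mm^3), mean voxel count and
#' standard error, a one-way ANOVA omnibus p across groups, and pairwise
#' Fisher's protected least-significant-difference contrasts. "Protected"
#' means pairwise contrasts are only reported when the omnibus p is below
#' `alpha`; otherwise their columns are `NA`. Rows are rank-ordered by
#' omnibus p (ties broken by region id).
#'
#' @param volumes list of per-subject [compute_region_volumes()] data.frames.
#' @param groups group label per subject.
#' @param alpha protection level for the post hoc contrasts (default 0.05).
#' @return data.frame with per-group `<g>_mean_volume_mm3`,
#'   `<g>_mean_voxel_count`, `<g>_se`, plus `p_value` and protected pairwise
#'   `p_<g1>_vs_<g2>` columns; attribute `flagged` lists regions with groups
#'   of a single subject (SE undefined).
#' @export
volume_compare <- function(volumes, groups, alpha = 0.05) {
  groups <- if (is.factor(groups)) groups else factor(groups, levels = unique(groups))
  if (length(volumes) != length(groups))
    stop("one group label per subject required")
  lv <- levels(groups)
  ids <- volumes[[1]]$id
  vol <- vapply(volumes, function(tb) tb$volume_mm3[match(ids, tb$id)],
                numeric(length(ids)))
  vox <- vapply(volumes, function(tb) tb$voxel_count[match(ids, tb$id)],
                numeric(length(ids)))
  vol <- matrix(vol, nrow = length(ids)); vox <- matrix(vox, nrow = length(ids))
  singular <- any(table(groups) < 2L)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  flagged <- integer(0)
  rows <- lapply(seq_along(ids), function(r) {
    v <- vol[r, ]
    row <- list(id = ids[r], name = volumes[[1]]$name[r])
    for (g in lv) {
      vg <- v[groups == g]
      row[[paste0(g, "_mean_volume_mm3")]] <- mean(vg)
      row[[paste0(g, "_mean_voxel_count")]] <- mean(vox[r, groups == g])
      row[[paste0(g, "_se")]] <- if (length(vg) > 1L) stats::sd(vg) / sqrt(length(vg)) else NA_real_
    }
    if (stats::var(v) == 0) {
      row$p_value <- 1
      for (pr in pairs) row[[paste0("p_", pr[1], "_vs_", pr[2])]] <- NA_real_
    } else {
      lsd <- fisher_lsd(v, groups)
      row$p_value <- lsd$omnibus_p
      protected <- !is.na(lsd$omnibus_p) && lsd$omnibus_p < alpha
      for (k in seq_along(pairs)) {
        pr <- pairs[[k]]
        row[[paste0("p_", pr[1], "_vs_", pr[2])]] <-
          if (protected) lsd$pairwise$p[k] else NA_real_
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$id), , drop = FALSE]
  if (singular) attr(out, "flagged") <- "groups with a single subject: SE undefined"
  out
}

#' ROI mean time course as percent change from baseline
#'
#' Maps the atlas region back into subject space through the inverse of the
#' subject's transform, averages the series over the region's voxels at each
#' acquisition, and expresses the trace as percent change from the
#' baseline-window mean (so the baseline acquisitions average to 0 exactly).
#'
#' @param series 4D array in subject space.
#' @param transform [affine_transform()] from subject to atlas space (its
#'   stored inverse carries the labels back). Use an identity transform when
#'   the series is already in atlas space.
#' @param atlas a [segmented_atlas()].
#' @param region region id to extract.
#' @param baseline_window inclusive 1-based `c(first, last)` acquisitions
#'   defining the baseline.
#' @return data.frame of class `roi_timecourse`: `acquisition`,
#'   `pct_change`.
#' @export
extract_timecourse <- function(series, transform, atlas, region,
                               baseline_window = c(1L, 20L)) {
  series <- as.array(series)
  if (!region %in% atlas$regions$id) stop("unknown region id: ", region)
  labels_sub <- apply_transform(atlas$labels, transform, "nearest",
                                direction = "inverse", fill = 0L)
  sel <- which(labels_sub == region)
  if (length(sel) == 0L) stop("region ", region, " empty after transform")
  nt <- dim(series)[4]
  if (baseline_window[1] < 1L || baseline_window[2] > nt ||
      baseline_window[1] > baseline_window[2])
    stop("invalid baseline window")
  nvox <- prod(dim(series)[1:3])
  mat <- matrix(series, nrow = nvox, ncol = nt)
  trace <- colMeans(mat[sel, , drop = FALSE])
  base <- mean(trace[window_idx(baseline_window)])
  if (base <= 0) stop("non-positive baseline mean in region ", region)
  out <- data.frame(acquisition = seq_len(nt),
                    pct_change = 100 * (trace - base) / base)
  class(out) <- c("roi_timecourse", "data.frame")
  out
}

#' Mixed repeated-measures ANOVA on ROI time courses
#'
#' Two-way mixed design: genotype as the between-subject factor, acquisition
#' as the within-subject factor, subject as the repeated unit. Reports the
#' genotype main effect (tested against between-subject variation), the
#' genotype x acquisition interaction (tested against the within-subject
#' residual), and Fisher's protected LSD group contrasts at each acquisition
#' (pairwise tests only where that acquisition's one-way omnibus ANOVA has
#' p < `alpha`).
#'
#' @param traces long-format data.frame with columns `subject`, `group`,
#'   `acquisition`, `pct_change` and a complete, balanced acquisition grid.
#' @param alpha protection level for the per-acquisition contrasts.
#' @return list with `main` (genotype F, df, p), `time`, `interaction`
#'   (each F, df, p), and `pairwise`: per-acquisition protected contrasts.
#' @export
timecourse_anova <- function(traces, alpha = 0.05) {
  need <- c("subject", "group", "acquisition", "pct_change")
  if (!all(need %in% names(traces))) stop("traces must have columns ", paste(need, collapse = ", "))
  tab <- table(traces$subject, traces$acquisition)
  if (any(tab != 1L)) stop("unbalanced acquisition grid across subjects")
  d <- data.frame(subject = factor(traces$subject),
                  group = factor(traces$group),
                  acq = factor(traces$acquisition),
                  y = traces$pct_change)
  fit <- stats::aov(y ~ group * acq + Error(subject), data = d)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    list(F = tab[i, "F value"], df1 = tab[i, "Df"],
         df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
         p = tab[i, "Pr(>F)"])
  }
  res <- list(main = pick(between, "group"),
              time = pick(within, "acq"),
              interaction = pick(within, "group:acq"))
  acqs <- sort(unique(traces$acquisition))
  pw <- lapply(acqs, function(a) {
    da <- d[traces$acquisition == a, ]
    if (stats::var(da$y) == 0)
      return(data.frame(acquisition = a, contrast = NA_character_,
                        t = NA_real_, p = NA_real_))
    lsd <- fisher_lsd(da$y, da$group)
    protected <- !is.na(lsd$omnibus_p) && lsd$omnibus_p < alpha
    data.frame(acquisition = a,
               contrast = lsd$pairwise$contrast,
               t = lsd$pairwise$t,
               p = if (protected) lsd$pairwise$p else NA_real_,
               stringsAsFactors = FALSE)
  })
  res$pairwise <- do.call(rbind, pw)
  res
}

#' Classify non-responders in a target region
#'
#' A subject is a non-responder when it has zero activated voxels in the
#' target ROI.
#'
#' @param tables list of per-subject [volume_of_activation()] data.frames.
#' @param region target region id.
#' @return logical vector, one entry per subject.
#' @export
non_responders <- function(tables, region) {
  vapply(tables, function(tb) {
    i <- match(region, tb$id)
    if (is.na(i)) stop("region ", region, " absent from a subject table")
    tb$activated_voxels[i] == 0L
  }, logical(1))
}

#' Plot group mean time courses with SEM ribbons
#'
#' @param traces long-format data.frame as in [timecourse_anova()].
#' @param file optional PNG path; when `NULL` plots to the active device.
#' @param main plot title.
#' @export
plot_timecourse <- function(traces, file = NULL, main = "ROI time course") {
  agg_m <- tapply(traces$pct_change, list(traces$acquisition, traces$group), mean)
  agg_se <- tapply(traces$pct_change, list(traces$acquisition, traces$group),
                   function(v) stats::sd(v) / sqrt(length(v)))
  acq <- as.numeric(rownames(agg_m))
  if (!is.null(file)) grDevices::png(file, width = 900, height = 600)
  graphics::matplot(acq, agg_m, type = "l", lty = 1, lwd = 2,
                    xlab = "acquisition", ylab = "% BOLD change", main = main)
  for (j in seq_len(ncol(agg_m))) {
    ok <- is.finite(agg_se[, j]) & agg_se[, j] > 0
    if (any(ok))  # arrows shorter than device resolution warn harmlessly
      suppressWarnings(
        graphics::arrows(acq[ok], agg_m[ok, j] - agg_se[ok, j],
                         acq[ok], agg_m[ok, j] + agg_se[ok, j],
                         length = 0.02, angle = 90, code = 3, col = j))
  }
  graphics::legend("topleft", legend = colnames(agg_m), col = seq_len(ncol(agg_m)),
                   lty = 1, lwd = 2, bty = "n")
  if (!is.null(file)) { grDevices::dev.off(); return(invisible(file)) }
  invisible(NULL)
}
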