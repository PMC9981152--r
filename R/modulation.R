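#' Zone specification for modulation indices
#'
#' Two conventions for assigning grid positions to figure, background, and
#' border zones on the 16 x 8 grid:
#' * `"results"`: figure zone is the central 2 x 2 block of positions
#'   (40 trials at 10 repeats); background is the leftmost and rightmost
#'   columns (2 x 8 positions, 160 trials); border zones are single columns
#'   (defaults 4 and 12, 80 trials each).
#' * `"methods"`: figure zone is the 2 x 2 block nearest the cell's fitted
#'   RF center; background is every position farther than 1.5 x the RF
#'   width from the RF center (RF width = 2 * geometric mean of the fitted
#'   sigmas).
#'
#' @param convention `"results"` or `"methods"`.
#' @param left_border_column,right_border_column border-zone columns.
#' @param background_distance_factor the 1.5x rule of the methods
#'   convention.
#' @export
zone_spec <- function(convention = c("results", "methods"),
                      left_border_column = 4L, right_border_column = 12L,
                      background_distance_factor = 1.5) {
  convention <- match.arg(convention)
  if (left_border_column == right_border_column) {
    stop("border columns must be distinct")
  }
  structure(list(convention = convention,
                 left_border_column = as.integer(left_border_column),
                 right_border_column = as.integer(right_border_column),
                 background_distance_factor = background_distance_factor),
            class = "zone_spec")
}

#' Label trials by zone
#'
#' Assigns each trial of one condition-variant (or all trials) to
#' figure / background / left_border / right_border / other according to
#' where the figure was centered on that trial.
#'
#' @param trial_table trial table with `az_bin`, `el_bin`.
#' @param grid a [position_grid()].
#' @param zone a [zone_spec()].
#' @param rf_fit an `rf_fit` (required by the `"methods"` convention);
#'   its center must be expressed in grid-bin units of this grid.
#' @return character vector of zone labels, one per trial, with a
#'   `counts` attribute.
#' @export
label_trials_by_zone <- function(trial_table, grid, zone = zone_spec(),
                                 rf_fit = NULL) {
  az <- trial_table$az_bin
  el <- trial_table$el_bin
  labels <- rep("other", nrow(trial_table))

  if (zone$convention == "results") {
    mid_az <- c(grid$n_azimuth / 2, grid$n_azimuth / 2 + 1)
    mid_el <- c(grid$n_elevation / 2, grid$n_elevation / 2 + 1)
    labels[az %in% mid_az & el %in% mid_el] <- "figure"
    labels[az %in% c(1L, grid$n_azimuth)] <- "background"
  } else {
    if (is.null(rf_fit)) {
      stop("the 'methods' convention requires an RF fit")
    }
    cx <- rf_fit$center[["x0"]]
    cy <- rf_fit$center[["y0"]]
    # 2 x 2 block of positions nearest the RF center
    ax <- pmin(pmax(floor(cx), 1L), grid$n_azimuth - 1L)
    ay <- pmin(pmax(floor(cy), 1L), grid$n_elevation - 1L)
    labels[az %in% c(ax, ax + 1L) & el %in% c(ay, ay + 1L)] <- "figure"
    rf_width <- 2 * sqrt(prod(rf_fit$widths))
    d <- sqrt((az - cx)^2 + (el - cy)^2)
    labels[d > zone$background_distance_factor * rf_width] <- "background"
  }
  labels[az == zone$left_border_column] <- "left_border"
  labels[az == zone$right_border_column] <- "right_border"
  structure(labels, counts = table(factor(
    labels, levels = c("figure", "background", "left_border", "right_border",
                       "other"))))
}

#' Figure-ground and border-ownership modulation indices
#'
#' Normalized difference `(a - b) / (a + b)` of two nonnegative zone-mean
#' responses; lies in `[-1, 1]` and flips sign when the zones are swapped.
#' `compute_fgm` contrasts figure versus background responses,
#' `compute_bom` left-border versus right-border responses.
#'
#' @param r_fig,r_back,r_left,r_right nonnegative zone means, not both zero.
#' @export
compute_fgm <- function(r_fig, r_back) {
  if (r_fig < 0 || r_back < 0) stop("zone means must be nonnegative")
  if (r_fig + r_back == 0) stop("both zone means are zero; index undefined")
  (r_fig - r_back) / (r_fig + r_back)
}

#' @rdname compute_fgm
#' @export
compute_bom <- function(r_left, r_right) compute_fgm(r_left, r_right)

# Zone means of trial means, averaged across the two within-condition
# patterns: one (mean over variant-1 zone trials + mean over variant-2 zone
# trials) / 2 per zone.
zone_mean <- function(responses, labels, variants, zone_name) {
  vals <- vapply(sort(unique(variants)), function(v) {
    sel <- labels == zone_name & variants == v
    if (!any(sel)) return(NA_real_)
    mean(responses[sel])
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Modulation index of one cell for one condition
#'
#' Pools the condition's two pattern variants: the index is computed from
#' zone means of trial means, averaged across the two patterns. Returns the
#' index together with its bootstrap p-value.
#'
#' @param responses response vector over trials (one cell).
#' @param trial_table the matching trial table.
#' @param grid a [position_grid()].
#' @param condition condition to analyze.
#' @param index `"fgm"` or `"bom"`.
#' @param zone a [zone_spec()]; `rf_fit` as in [label_trials_by_zone()].
#' @param n_shuffles bootstrap shuffles of trial identity.
#' @param seed bootstrap seed.
#' @param rf_fit optional `rf_fit` for the methods convention.
#' @param variant restrict to a single pattern variant instead of pooling
#'   both (used when each cell contributes one index per stimulus variant).
#' @return a `modulation_result` list: `index_value, r_a, r_b, n_a, n_b,
#'   p_value, condition, index`.
#' @export
modulation_index <- function(responses, trial_table, grid, condition,
                             index = c("fgm", "bom"), zone = zone_spec(),
                             n_shuffles = 500, seed = 1L, rf_fit = NULL,
                             variant = NULL) {
  index <- match.arg(index)
  sel <- trial_table$condition == condition
  if (!is.null(variant)) sel <- sel & trial_table$variant == variant
  if (!any(sel)) stop("no trials for condition ", condition)
  tt <- trial_table[sel, ]
  r <- responses[sel]
  labels <- label_trials_by_zone(tt, grid, zone, rf_fit = rf_fit)
  zones <- if (index == "fgm") c("figure", "background")
           else c("left_border", "right_border")
  use <- labels %in% zones
  if (sum(labels[use] == zones[1]) < 2 || sum(labels[use] == zones[2]) < 2) {
    stop("need at least 2 trials in each zone")
  }
  a <- zone_mean(r, labels, tt$variant, zones[1])
  b <- zone_mean(r, labels, tt$variant, zones[2])
  obs <- compute_fgm(a, b)
  p <- bootstrap_significance(r[use], labels[use], tt$variant[use],
                              zones, observed = obs,
                              n_shuffles = n_shuffles, seed = seed)
  structure(list(index = index, condition = condition, index_value = obs,
                 r_a = a, r_b = b,
                 n_a = sum(labels == zones[1]), n_b = sum(labels == zones[2]),
                 p_value = p),
            class = "modulation_result")
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf("<modulation_result> %s (%s) = %.3f (p = %.3g; zones %d/%d trials)\n",
              toupper(x$index), x$condition, x$index_value, x$p_value,
              x$n_a, x$n_b))
  invisible(x)
}

#' Bootstrap p-value for a modulation index
#'
#' Shuffles trial identity among the two zones' trials (within the whole
#' pooled set), recomputes the index, and reports the two-sided p-value:
#' the fraction of shuffles with `|index| >= |observed|`, with the
#' +1/(n+1) small-sample correction. Reproducible under `seed`.
#'
#' @param responses responses of the zone trials only.
#' @param labels zone label per trial.
#' @param variants pattern variant per trial.
#' @param zones the two zone names `(a, b)`.
#' @param observed the observed index.
#' @param n_shuffles number of shuffles (500 canonically).
#' @param seed shuffle seed.
#' @export
bootstrap_significance <- function(responses, labels, variants, zones,
                                   observed, n_shuffles = 500, seed = 1L) {
  n <- length(responses)
  vs <- sort(unique(variants))
  # per variant x zone row selectors, reused across shuffles
  sels <- lapply(vs, function(v) {
    lapply(zones, function(z) which(labels == z & variants == v))
  })
  with_seed(seed, {
    perm <- matrix(0L, n, n_shuffles)
    for (b in seq_len(n_shuffles)) perm[, b] <- sample.int(n)
    Rp <- matrix(responses[perm], n, n_shuffles)
    zmean <- function(zi) {
      acc <- matrix(NA_real_, length(vs), n_shuffles)
      for (k in seq_along(vs)) {
        rows <- sels[[k]][[zi]]
        if (length(rows) > 0) acc[k, ] <- colSums(Rp[rows, , drop = FALSE]) /
            length(rows)
      }
      colMeans(acc, na.rm = TRUE)
    }
    a <- zmean(1)
    bb <- zmean(2)
    idx <- ifelse(a + bb == 0, 0, (a - bb) / (a + bb))
    exceed <- sum(abs(idx) >= abs(observed) - 1e-12)
    (exceed + 1) / (n_shuffles + 1)
  })
}

#' Significance counts across the six condition-variants
#'
#' Given per-cell p-values for each of the six stimulus variants, counts in
#' how many variants each cell is significant at `alpha` and compares the
#' histogram of counts with the Binomial(6, alpha) chance curve (the
#' false-positive expectation after six comparisons).
#'
#' @param p_matrix cells x variants matrix of p-values.
#' @param alpha significance level per comparison.
#' @return list with `counts` per cell, `histogram` over 0..n_variants,
#'   `chance` (binomial mass function), and `fraction` (observed fraction
#'   of cells per count).
#' @export
count_significant_conditions <- function(p_matrix, alpha = 0.05) {
  if (is.vector(p_matrix)) p_matrix <- matrix(p_matrix, nrow = 1)
  k <- ncol(p_matrix)
  counts <- rowSums(p_matrix < alpha)
  histogram <- tabulate(counts + 1L, nbins = k + 1L)
  names(histogram) <- 0:k
  list(counts = counts, histogram = histogram,
       fraction = histogram / nrow(p_matrix),
       chance = stats::dbinom(0:k, k, alpha))
}

#' Zone-resolved response time courses
#'
#' Mean +/- SEM time courses for figure, ground, and border trials, with a
#' per-bin one-sided two-sample t-test flagging bins where the figure
#' response significantly exceeds the ground response.
#'
#' @param timecourses trials x bins matrix of time-resolved responses for
#'   one cell.
#' @param labels zone label per trial (from [label_trials_by_zone()]).
#' @param alpha per-bin significance level (0.01 canonically).
#' @return list of per-zone `mean` and `sem` matrices (zones x bins), the
#'   per-bin t statistics and p-values, and logical `flags`.
#' @export
compute_zone_timecourses <- function(timecourses, labels, alpha = 0.01) {
  zones <- c("figure", "background", "left_border", "right_border")
  present <- zones[zones %in% labels]
  n_bins <- ncol(timecourses)
  mean_tc <- sem_tc <- matrix(NA_real_, length(present), n_bins,
                              dimnames = list(present, NULL))
  for (z in present) {
    M <- timecourses[labels == z, , drop = FALSE]
    if (nrow(M) < 2) stop("fewer than 2 trials in zone ", z)
    mean_tc[z, ] <- colMeans(M)
    sem_tc[z, ] <- apply(M, 2, stats::sd) / sqrt(nrow(M))
  }
  tstat <- pval <- rep(NA_real_, n_bins)
  if (all(c("figure", "background") %in% present)) {
    Fg <- timecourses[labels == "figure", , drop = FALSE]
    Bg <- timecourses[labels == "background", , drop = FALSE]
    for (b in seq_len(n_bins)) {
      if (stats::sd(Fg[, b]) == 0 && stats::sd(Bg[, b]) == 0) {
        # degenerate bin: identical flat responses are never flagged
        tstat[b] <- 0; pval[b] <- 1
        if (mean(Fg[, b]) > mean(Bg[, b])) { tstat[b] <- Inf; pval[b] <- 0 }
        next
      }
      tt <- stats::t.test(Fg[, b], Bg[, b], alternative = "greater")
      tstat[b] <- unname(tt$statistic)
      pval[b] <- tt$p.value
    }
  }
  list(mean = mean_tc, sem = sem_tc, t_statistic = tstat, p_value = pval,
       flags = !is.na(pval) & pval < alpha)
}

#' Per-cell modulation results table
#'
#' Convenience wrapper computing FGM and BOM (results convention by
#' default) for every neuron and condition of a simulated dataset.
#'
#' @param dataset an `fg_dataset`.
#' @param index `"fgm"` or `"bom"`.
#' @param zone a [zone_spec()].
#' @param n_shuffles,seed bootstrap parameters.
#' @param neurons neuron subset.
#' @return data.frame: cell, condition, index, value, r_a, r_b, n_a, n_b, p.
#' @export
modulation_table <- function(dataset, index = c("fgm", "bom"),
                             zone = zone_spec(), n_shuffles = 500, seed = 1L,
                             neurons = seq_len(nrow(dataset$responses))) {
  index <- match.arg(index)
  conds <- unique(dataset$trials$condition)
  out <- list()
  for (n in neurons) {
    for (cond in conds) {
      m <- modulation_index(dataset$responses[n, ], dataset$trials,
                            dataset$grid, cond, index = index, zone = zone,
                            n_shuffles = n_shuffles,
                            seed = derive_seed(seed, n * 101L + match(cond, conds)))
      out[[length(out) + 1]] <- data.frame(
        cell = n, condition = cond, index = index, value = m$index_value,
        r_a = m$r_a, r_b = m$r_b, n_a = m$n_a, n_b = m$n_b, p = m$p_value)
    }
  }
  do.call(rbind, out)
}
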