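#' Trial responses from a continuous recording
#'
#' Collapses a recording into one scalar response per neuron per trial: for
#' spike trains, the spike count in a 50-250 ms post-onset window; for
#' trace matrices (e.g. deconvolved calcium), the mean across the trial's
#' frames.
#'
#' @param recording either a list of per-neuron spike-time vectors
#'   (seconds) or a neurons x timebins matrix with attribute-free regular
#'   sampling described by `trace_rate_hz`.
#' @param trial_table data.frame with `onset_s` per trial.
#' @param window_ms response window after trial onset (spike input).
#' @param trial_duration_s trial length (trace input).
#' @param trace_rate_hz sampling rate of the trace matrix.
#' @return neurons x trials matrix of nonnegative responses.
#' @export
compute_trial_responses <- function(recording, trial_table,
                                    window_ms = c(50, 250),
                                    trial_duration_s = 0.25,
                                    trace_rate_hz = NULL) {
  onsets <- trial_table$onset_s
  if (is.list(recording)) {
    w <- window_ms / 1000
    out <- t(vapply(recording, function(st) {
      vapply(onsets, function(t0) {
        sum(st >= t0 + w[1] & st < t0 + w[2])
      }, numeric(1))
    }, numeric(length(onsets))))
    return(out)
  }
  if (is.matrix(recording)) {
    if (is.null(trace_rate_hz)) stop("`trace_rate_hz` required for trace input")
    n_bins <- ncol(recording)
    out <- matrix(0, nrow(recording), length(onsets))
    for (j in seq_along(onsets)) {
      b0 <- floor(onsets[j] * trace_rate_hz) + 1
      b1 <- min(n_bins, ceiling((onsets[j] + trial_duration_s) * trace_rate_hz))
      if (b0 > n_bins) stop("trial ", j, " lies outside the recording span")
      out[, j] <- rowMeans(recording[, b0:b1, drop = FALSE])
    }
    return(out)
  }
  stop("`recording` must be a list of spike-time vectors or a trace matrix")
}

#' Per-neuron figure map
#'
#' Mean response at each of the grid's figure positions for one
#' condition-variant: `values[el, az]` is the mean over that position's
#' trials. Missing positions are an error (no silent interpolation).
#'
#' @param responses neurons x trials matrix, or a vector for one neuron.
#' @param trial_table trial table with `condition, variant, az_bin, el_bin`.
#' @param grid a [position_grid()].
#' @param condition,variant which condition-variant to map.
#' @param neuron row index when `responses` is a matrix.
#' @return a `figure_map`: matrix `n_elevation x n_azimuth` with `n_trials`
#'   attribute.
#' @export
build_figure_map <- function(responses, trial_table, grid, condition,
                             variant, neuron = 1L) {
  r <- if (is.matrix(responses)) responses[neuron, ] else responses
  if (length(r) != nrow(trial_table)) {
    stop("responses and trial table have different trial counts")
  }
  sel <- trial_table$condition == condition & trial_table$variant == variant
  if (!any(sel)) stop("no trials for ", condition, " variant ", variant)
  tt <- trial_table[sel, ]
  rv <- r[sel]
  idx <- (tt$az_bin - 1L) * grid$n_elevation + tt$el_bin
  means <- tapply(rv, idx, mean)
  counts <- tapply(rv, idx, length)
  values <- matrix(NA_real_, grid$n_elevation, grid$n_azimuth)
  n_trials <- matrix(0L, grid$n_elevation, grid$n_azimuth)
  values[as.integer(names(means))] <- means
  n_trials[as.integer(names(counts))] <- counts
  if (anyNA(values)) {
    stop(sum(is.na(values)), " grid positions have no trials for ",
         condition, " variant ", variant)
  }
  structure(values, n_trials = n_trials, condition = condition,
            variant = variant, neuron = neuron, class = "figure_map")
}

#' @export
print.figure_map <- function(x, ...) {
  cat(sprintf("<figure_map> %s v%d, neuron %d: %d x %d positions, range [%.3g, %.3g]\n",
              attr(x, "condition"), attr(x, "variant"), attr(x, "neuron"),
              nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

#' Pearson correlation between two figure maps
#'
#' @param map_a,map_b matrices of equal dimensions; constant maps are an
#'   error (r undefined).
#' @export
correlate_maps <- function(map_a, map_b) {
  if (!all(dim(map_a) == dim(map_b))) stop("maps have different dimensions")
  if (stats::sd(as.vector(map_a)) == 0 || stats::sd(as.vector(map_b)) == 0) {
    stop("correlation undefined for a constant map")
  }
  stats::cor(as.vector(map_a), as.vector(map_b))
}

#' Cross-condition map consistency
#'
#' Mean Pearson correlation over all unordered pairs of a neuron's maps for
#' the six condition-variants (15 pairs for 6 maps). A texture-invariant
#' figure response gives a clearly positive mean; texture-bound cells
#' center near zero.
#'
#' @param maps list of equally sized matrices (one per condition-variant).
#' @return list with the mean `consistency` and the per-pair correlations.
#' @export
condition_consistency <- function(maps) {
  k <- length(maps)
  if (k < 2) stop("need at least two maps")
  pairs <- utils::combn(k, 2)
  r <- apply(pairs, 2, function(ij) correlate_maps(maps[[ij[1]]],
                                                   maps[[ij[2]]]))
  list(consistency = mean(r), pair_r = r)
}

#' Jaccard overlap of two cell masks
#'
#' `J(A, B) = |A intersect B| / |A union B|` on binary spatial footprints.
#'
#' @param mask_a,mask_b logical matrices on a common registered grid.
#' @export
jaccard_index <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("masks have different dimensions")
  u <- sum(mask_a | mask_b)
  if (u == 0) stop("both masks are empty")
  sum(mask_a & mask_b) / u
}

#' Match cells across sessions by mask overlap
#'
#' Computes all pairwise Jaccard indices and greedily assigns one-to-one
#' matches in order of descending overlap; a pair is a match when J exceeds
#' `threshold` (0.5 by convention: half-overlapping equal-area masks give
#' J = 1/3 and are *not* matched).
#'
#' @param masks_a,masks_b lists of logical matrices (registered to a common
#'   grid).
#' @param threshold minimum Jaccard index for a match.
#' @return data.frame of matched pairs `(a, b, jaccard)`.
#' @export
match_cells_across_sessions <- function(masks_a, masks_b, threshold = 0.5) {
  if (length(masks_a) == 0 || length(masks_b) == 0) stop("empty mask set")
  J <- outer(seq_along(masks_a), seq_along(masks_b),
             Vectorize(function(i, j) jaccard_index(masks_a[[i]],
                                                    masks_b[[j]])))
  ord <- order(J, decreasing = TRUE)
  used_a <- logical(length(masks_a))
  used_b <- logical(length(masks_b))
  out <- list()
  for (k in ord) {
    if (J[k] <= threshold) break
    i <- ((k - 1) %% length(masks_a)) + 1
    j <- ((k - 1) %/% length(masks_a)) + 1
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    out[[length(out) + 1]] <- data.frame(a = i, b = j, jaccard = J[k])
  }
  if (length(out) == 0) {
    return(data.frame(a = integer(0), b = integer(0), jaccard = numeric(0)))
  }
  do.call(rbind, out)
}

#' Matched versus shuffled map-correlation distributions
#'
#' For matched cell pairs, the correlation between their figure maps across
#' sessions; for a shuffled control, the same number of random non-matched
#' pairings. Reliable, stable responses make the matched distribution
#' stochastically larger (summarized by the two-sample KS statistic).
#'
#' @param maps_a,maps_b lists of figure maps per session.
#' @param matches data.frame from [match_cells_across_sessions()].
#' @param n_shuffled number of shuffled control pairs (default: as many as
#'   matched).
#' @param seed shuffle seed.
#' @return list with `matched_r`, `shuffled_r`, `ks_statistic`, `p_value`.
#' @export
matched_vs_shuffled <- function(maps_a, maps_b, matches,
                                n_shuffled = nrow(matches), seed = 1L) {
  if (nrow(matches) == 0) stop("no matched pairs")
  matched_r <- mapply(function(i, j) correlate_maps(maps_a[[i]], maps_b[[j]]),
                      matches$a, matches$b)
  matched_key <- paste(matches$a, matches$b)
  shuffled_r <- with_seed(seed, {
    out <- numeric(0)
    guard <- 0
    while (length(out) < n_shuffled && guard < 100 * n_shuffled) {
      i <- sample(length(maps_a), 1)
      j <- sample(length(maps_b), 1)
      guard <- guard + 1
      if (paste(i, j) %in% matched_key) next
      out <- c(out, correlate_maps(maps_a[[i]], maps_b[[j]]))
    }
    out
  })
  # alternative = "less": the matched CDF lies below the shuffled CDF,
  # i.e. matched correlations are stochastically greater
  ks <- suppressWarnings(stats::ks.test(matched_r, shuffled_r,
                                        alternative = "less"))
  list(matched_r = matched_r, shuffled_r = shuffled_r,
       ks_statistic = unname(ks$statistic), p_value = ks$p.value)
}

#' Export figure maps as long-format CSV
#'
#' Columns: neuron, condition, variant, az, el, mean, n.
#'
#' @param dataset an `fg_dataset`.
#' @param path output path.
#' @param neurons which neurons to export (default all).
#' @export
write_figure_maps_csv <- function(dataset, path,
                                  neurons = seq_len(nrow(dataset$responses))) {
  grid <- dataset$grid
  cv <- unique(dataset$trials[, c("condition", "variant")])
  rows <- list()
  for (n in neurons) {
    for (k in seq_len(nrow(cv))) {
      m <- build_figure_map(dataset$responses, dataset$trials, grid,
                            cv$condition[k], cv$variant[k], neuron = n)
      rows[[length(rows) + 1]] <- data.frame(
        neuron = n, condition = cv$condition[k], variant = cv$variant[k],
        az = rep(seq_len(grid$n_azimuth), each = grid$n_elevation),
        el = rep(seq_len(grid$n_elevation), times = grid$n_azimuth),
        mean = as.vector(unclass(m)),
        n = as.vector(attr(m, "n_trials")))
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
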