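#' Decoder configuration
#'
#' Cross-validated ridge decoding of the figure's azimuth bin (1..16,
#' treated as a continuous regression target) from population responses:
#' 50/50 train/test splits, the ridge penalty chosen on the training half by
#' an internal 50/50 split over a logarithmic grid, results averaged over
#' `n_iterations` resamplings of both the trial split and the neuron
#' subset.
#'
#' @param train_fraction fraction of trials used for training.
#' @param n_iterations resampling iterations (100 canonically).
#' @param penalty_grid ridge penalties for internal cross-validation.
#' @param neuron_counts neuron-subsample sizes for sweep curves.
#' @param seed resampling seed.
#' @export
decoding_config <- function(train_fraction = 0.5, n_iterations = 100,
                            penalty_grid = 10^seq(3, -3, length.out = 10),
                            neuron_counts = c(5, 20, 100, 200),
                            seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must be in (0, 1)")
  }
  stop_if_not_positive(n_iterations, "n_iterations")
  structure(list(train_fraction = train_fraction,
                 n_iterations = as.integer(n_iterations),
                 penalty_grid = sort(penalty_grid, decreasing = TRUE),
                 neuron_counts = neuron_counts, seed = as.integer(seed)),
            class = "decoding_config")
}

# One ridge fit with internal penalty selection: split the training set
# 50/50, pick the penalty with the lowest validation error, refit on the
# full training set.
ridge_fit_predict <- function(x_train, y_train, x_test, penalty_grid) {
  n <- nrow(x_train)
  inner <- sample.int(n, floor(n / 2))
  sds <- apply(x_train[inner, , drop = FALSE], 2, stats::sd)
  lambda_sel <- if (all(sds == 0)) {
    penalty_grid[1]
  } else {
    fit_inner <- glmnet::glmnet(x_train[inner, , drop = FALSE],
                                y_train[inner], alpha = 0,
                                lambda = penalty_grid)
    pred <- stats::predict(fit_inner, x_train[-inner, , drop = FALSE])
    errs <- colMeans((pred - y_train[-inner])^2)
    penalty_grid[which.min(errs)]
  }
  if (all(apply(x_train, 2, stats::sd) == 0)) {
    return(rep(mean(y_train), nrow(x_test)))
  }
  fit <- glmnet::glmnet(x_train, y_train, alpha = 0, lambda = penalty_grid)
  as.vector(stats::predict(fit, x_test, s = lambda_sel))
}

r_squared <- function(y, y_hat) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("labels are constant; r^2 undefined")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Cross-validated position decoding
#'
#' Decodes a continuous label (canonically the azimuth bin) from a
#' neurons x trials response matrix. Each iteration resamples the neuron
#' subset (when `n_neurons` is smaller than the population) and the 50/50
#' trial split; the reported value is the held-out coefficient of
#' determination `r^2 = 1 - SS_res / SS_tot` (can be negative), averaged
#' over iterations with a t-based 95% CI.
#'
#' @param responses neurons x trials matrix.
#' @param labels numeric label per trial (azimuth bin 1..16).
#' @param config a [decoding_config()].
#' @param n_neurons neuron-subsample size (default: all).
#' @param permute_labels decode a permuted-label null instead (labels are
#'   permuted once per iteration before splitting).
#' @return a `decoding_result`: `variance_explained` (mean r^2), `ci95`,
#'   `per_iteration`, `n_neurons`.
#' @export
fit_position_decoder <- function(responses, labels, config = decoding_config(),
                                 n_neurons = nrow(responses),
                                 permute_labels = FALSE) {
  if (ncol(responses) != length(labels)) {
    stop("`labels` must have one value per trial")
  }
  if (n_neurons > nrow(responses)) {
    stop("`n_neurons` exceeds the population size")
  }
  if (length(unique(labels)) < 2) stop("labels are single-valued")
  n_trials <- length(labels)
  r2 <- with_seed(config$seed, {
    vapply(seq_len(config$n_iterations), function(it) {
      cells <- if (n_neurons < nrow(responses)) {
        sample(nrow(responses), n_neurons)
      } else seq_len(nrow(responses))
      y <- if (permute_labels) sample(labels) else labels
      tr <- sample.int(n_trials, round(config$train_fraction * n_trials))
      if (length(unique(y[tr])) < 2 || length(unique(y[-tr])) < 2) {
        return(NA_real_)
      }
      X <- t(responses[cells, , drop = FALSE])
      y_hat <- ridge_fit_predict(X[tr, , drop = FALSE], y[tr],
                                 X[-tr, , drop = FALSE], config$penalty_grid)
      r_squared(y[-tr], y_hat)
    }, numeric(1))
  })
  r2 <- r2[!is.na(r2)]
  se <- stats::sd(r2) / sqrt(length(r2))
  structure(list(variance_explained = mean(r2),
                 ci95 = mean(r2) + c(-1, 1) * stats::qt(0.975, length(r2) - 1) * se,
                 per_iteration = r2, n_neurons = n_neurons,
                 permuted = permute_labels),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> r^2 = %.3f [%.3f, %.3f] (%d neurons, %d iterations%s)\n",
              x$variance_explained, x$ci95[1], x$ci95[2], x$n_neurons,
              length(x$per_iteration),
              if (isTRUE(x$permuted)) ", permuted labels" else ""))
  invisible(x)
}

#' Decode an arbitrary feature matrix
#'
#' Identical pipeline to [fit_position_decoder()] applied to any
#' units x trials feature matrix (e.g. externally computed network-layer
#' activations).
#'
#' @param features units x trials numeric matrix (finite).
#' @inheritParams fit_position_decoder
#' @export
decode_feature_matrix <- function(features, labels,
                                  config = decoding_config(),
                                  n_neurons = nrow(features),
                                  permute_labels = FALSE) {
  if (!all(is.finite(features))) stop("`features` must be finite")
  fit_position_decoder(features, labels, config = config,
                       n_neurons = n_neurons,
                       permute_labels = permute_labels)
}

#' Decoding performance versus neuron count, per condition
#'
#' Within each condition the two pattern variants' trials are pooled before
#' splitting, so the decoder must generalize across the two carrier
#' patterns; curves are monotone non-decreasing in the neuron count up to
#' sampling error.
#'
#' @param dataset an `fg_dataset`.
#' @param conditions conditions to decode (default: all present).
#' @param config a [decoding_config()]; `neuron_counts` sets the sweep.
#' @param permute_labels decode the permuted-label null instead.
#' @return data.frame: condition, n_neurons, r2, ci_lo, ci_hi.
#' @export
decoding_curve <- function(dataset, conditions = NULL,
                           config = decoding_config(),
                           permute_labels = FALSE) {
  if (is.null(conditions)) conditions <- unique(dataset$trials$condition)
  missing <- setdiff(conditions, unique(dataset$trials$condition))
  if (length(missing) > 0) {
    stop("conditions absent from the dataset: ", paste(missing, collapse = ", "))
  }
  counts <- config$neuron_counts[config$neuron_counts <= nrow(dataset$responses)]
  out <- list()
  for (cond in conditions) {
    sel <- dataset$trials$condition == cond
    R <- dataset$responses[, sel, drop = FALSE]
    y <- dataset$trials$az_bin[sel]
    for (k in counts) {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, match(cond, conditions) * 1000L + k)
      res <- fit_position_decoder(R, y, config = cfg, n_neurons = k,
                                  permute_labels = permute_labels)
      out[[length(out) + 1]] <- data.frame(
        condition = cond, n_neurons = k, r2 = res$variance_explained,
        ci_lo = res$ci95[1], ci_hi = res$ci95[2])
    }
  }
  do.call(rbind, out)
}

#' Left/right generalization observer
#'
#' Mirrors the behavioral pattern-generalization test on a model
#' population: a regularized linear classifier is trained to report the
#' side (left/right) of the figure from responses to the *training*
#' patterns and evaluated on responses to held-out *novel* patterns of the
#' same condition. Chance is 0.5.
#'
#' @param train_responses,test_responses neurons x trials matrices for the
#'   training-pattern and novel-pattern trials.
#' @param train_sides,test_sides `"left"`/`"right"` label per trial.
#' @param penalty ridge penalty of the linear readout.
#' @return list with `accuracy` (novel patterns), `train_accuracy`.
#' @export
side_generalization_test <- function(train_responses, train_sides,
                                     test_responses, test_sides,
                                     penalty = 1) {
  y <- as.numeric(train_sides == "right")
  if (length(unique(y)) < 2) stop("training set needs both sides")
  fit <- glmnet::glmnet(t(train_responses), y, family = "gaussian",
                        alpha = 0, lambda = penalty)
  pred_test <- as.vector(stats::predict(fit, t(test_responses))) > 0.5
  pred_train <- as.vector(stats::predict(fit, t(train_responses))) > 0.5
  list(accuracy = mean(pred_test == (test_sides == "right")),
       train_accuracy = mean(pred_train == (train_sides == "right")))
}

#' Export a decoding curve as CSV
#'
#' @param curve result of [decoding_curve()].
#' @param path output path.
#' @export
write_decoding_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
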