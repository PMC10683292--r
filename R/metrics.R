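# Evaluation metrics and dataset splitting.
#
# Conventions: metrics are computed per atom, pooled over the test set.
# MASE = MAE / MAE of the naive predictor (the constant training-set
# mean shift) on the same test atoms, which makes scores comparable
# across nuclei and solvents; sigma is the population standard
# deviation of the signed errors, so RMSE^2 = mean(error)^2 + sigma^2
# and sigma <= RMSE always.

#' Fit the naive mean-shift predictor
#'
#' The constant predictor equal to the training-set mean shift: the
#' reference in the MASE denominator and the weakest sensible baseline.
#'
#' @param data Training [shift_dataset()].
#' @return Object of class `naive_shift_model`.
#' @export
naive_shift_model <- function(data) {
  stopifnot(inherits(data, "shift_dataset"))
  shifts <- unlist(lapply(data$records, function(r) r$shifts$ppm))
  if (length(shifts) == 0L)
    stop("no assigned shifts in training data", call. = FALSE)
  structure(list(mean_shift = mean(shifts), n_shifts = length(shifts),
                 nucleus = data$nucleus),
            class = "naive_shift_model")
}

#' @export
print.naive_shift_model <- function(x, ...) {
  cat(sprintf("<naive_shift_model: predicts %.3f ppm (%s mean of %d training shifts)>\n",
              x$mean_shift, x$nucleus, x$n_shifts))
  invisible(x)
}

#' @export
predict.naive_shift_model <- function(object, newdata, ...) {
  if (inherits(newdata, "shift_record"))
    newdata <- shift_dataset(list(newdata), newdata$nucleus)
  out <- lapply(newdata$records, function(r) {
    if (nrow(r$shifts) == 0L) return(NULL)
    data.frame(molecule_id = r$molecule_id, atom_index = r$shifts$atom,
               true_shift_ppm = r$shifts$ppm,
               predicted_shift_ppm = object$mean_shift,
               matched_spheres = NA_integer_, method = "naive",
               missing_flag = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Molecule-level train/test split
#'
#' Partitions a dataset at the molecule level (all atoms of a molecule
#' land on the same side), with `round(test_fraction * n)` test
#' molecules, deterministic for a given seed.
#'
#' @param dataset A [shift_dataset()] of at least 4 molecules.
#' @param test_fraction Fraction of molecules in the test set
#'   (default 0.25, the 75:25 convention).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`.
#' @export
split_shift_dataset <- function(dataset, test_fraction = 0.25, seed = 1L) {
  n <- length(dataset)
  if (n < 4L) stop("dataset too small to split (need >= 4 molecules)",
                   call. = FALSE)
  stopifnot(test_fraction > 0, test_fraction < 1)
  n_test <- round(test_fraction * n)
  if (n_test < 1L || n_test >= n)
    stop("test fraction leaves an empty partition", call. = FALSE)
  test_idx <- with_seed(seed, sort(sample.int(n, n_test)))
  list(train = dataset[setdiff(seq_len(n), test_idx)],
       test = dataset[test_idx])
}

#' Compute the evaluation metrics of a prediction set
#'
#' Given aligned predictions and truths (missing predictions as `NA`),
#' computes MAE, RMSE, the population standard deviation of the signed
#' errors, and MASE relative to a naive-predictor MAE.  Missing entries
#' are excluded from the error statistics and reported as a percentage.
#'
#' @param predicted Numeric vector of predicted shifts (ppm), `NA` for
#'   missing predictions.
#' @param truth Numeric vector of true shifts (ppm), same length.
#' @param naive_mae MAE of the naive reference predictor on the same
#'   atoms (ppm); when `NULL`, MASE is reported as `NA`.
#' @return Object of class `shift_metrics`: list with `mae`, `rmse`,
#'   `mase`, `sigma`, `n_atoms`, `missing_percent`, `naive_mae`.
#' @export
#' @examples
#' compute_metrics(c(-1, 1, 0) + 10, c(10, 10, 10), naive_mae = 2)
compute_metrics <- function(predicted, truth, naive_mae = NULL) {
  stopifnot(length(predicted) == length(truth))
  if (length(predicted) == 0L)
    stop("no prediction/truth pairs", call. = FALSE)
  ok <- !is.na(predicted) & !is.na(truth)
  if (!any(ok))
    stop("all predictions missing; no pairs to evaluate", call. = FALSE)
  err <- predicted[ok] - truth[ok]
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  sigma <- sqrt(mean((err - mean(err))^2))
  mase <- NA_real_
  if (!is.null(naive_mae) && !is.na(naive_mae)) {
    if (naive_mae > 0) {
      mase <- mae / naive_mae
    } else {
      message("naive MAE is zero; MASE undefined")
    }
  }
  structure(list(mae = mae, rmse = rmse, mase = mase, sigma = sigma,
                 n_atoms = sum(ok),
                 missing_percent = 100 * mean(is.na(predicted)),
                 naive_mae = if (is.null(naive_mae)) NA_real_ else naive_mae),
            class = "shift_metrics")
}

#' @export
print.shift_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("MAE %s ppm | RMSE %s ppm | MASE %s | sigma %s ppm | n = %d",
              format(x$mae, digits = digits),
              format(x$rmse, digits = digits),
              format(x$mase, digits = digits),
              format(x$sigma, digits = digits), x$n_atoms))
  if (x$missing_percent > 0)
    cat(sprintf(" | missing %.2f%%", x$missing_percent))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.shift_metrics <- function(x, ...) {
  data.frame(mae = x$mae, rmse = x$rmse, mase = x$mase, sigma = x$sigma,
             n_atoms = x$n_atoms, missing_percent = x$missing_percent,
             naive_mae = x$naive_mae)
}

#' Evaluate a prediction table
#'
#' Computes [compute_metrics()] from a prediction data.frame (as
#' returned by the `predict()` methods), deriving the naive MAE from a
#' training dataset or fitted naive model evaluated on the same atoms.
#'
#' @param predictions Prediction data.frame with `true_shift_ppm` and
#'   `predicted_shift_ppm` columns.
#' @param naive A [naive_shift_model()], a training [shift_dataset()],
#'   or a numeric naive MAE; `NULL` leaves MASE unreported.
#' @return A `shift_metrics` object.
#' @export
evaluate_predictions <- function(predictions, naive = NULL) {
  truth <- predictions$true_shift_ppm
  naive_mae <- NULL
  if (inherits(naive, "shift_dataset")) naive <- naive_shift_model(naive)
  if (inherits(naive, "naive_shift_model")) {
    ok <- !is.na(truth)
    naive_mae <- mean(abs(naive$mean_shift - truth[ok]))
  } else if (is.numeric(naive)) {
    naive_mae <- naive
  }
  compute_metrics(predictions$predicted_shift_ppm, truth, naive_mae)
}
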