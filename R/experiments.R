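# Size-stratified evaluation experiments: learning curves over training
# sizes, matched-only comparisons (dropping molecules the HOSE lookup
# cannot predict), and k-fold hyperparameter search.
#
# Experiment bookkeeping: within one split seed the training subsets
# are nested across sizes (the size-100 subset is a prefix of the
# size-250 subset), which reduces curve variance; all methods at one
# (size, seed) cell share the identical training subset and the
# identical test set.

.fit_method <- function(method, train, config, s_max) {
  switch(method,
         naive = naive_shift_model(train),
         hose = hose_model(train, s_max = s_max),
         gnn = nmr_gnn(train, config = config),
         stop("unknown method: ", method, call. = FALSE))
}

.method_metrics <- function(fit, test, train) {
  pred <- predict(fit, test)
  evaluate_predictions(pred, naive = train)
}

#' Learning-curve experiment
#'
#' For each split seed, draws a 75:25 molecule-level train/test split,
#' then for each training size takes a nested random subset of the
#' training molecules, fits every requested method on it and evaluates
#' on the fixed test set.  The MASE denominator at each cell is the
#' naive mean predictor fitted on that cell's training subset, so all
#' methods within a cell share it.
#'
#' @param dataset A [shift_dataset()].
#' @param sizes Increasing vector of training sizes (molecules).
#' @param methods Subset of `c("naive", "hose", "gnn")`.
#' @param seeds Integer vector of split seeds (default `1:3`).
#' @param test_fraction Test fraction of the molecule-level split.
#' @param config [gnn_config()] for the GNN fits; its seed is offset by
#'   the split seed so repeated seeds give independent initialisations.
#' @param s_max HOSE sphere depth.
#' @param verbose Print progress.
#' @return Object of class `shift_learning_curve`: `results` is a tidy
#'   data.frame (method, size, seed, metric, value); `reports` holds
#'   the full `shift_metrics` objects.
#' @export
learning_curve <- function(dataset, sizes, methods = c("naive", "hose", "gnn"),
                           seeds = 1:3, test_fraction = 0.25,
                           config = gnn_config(), s_max = 6L,
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "shift_dataset"), length(sizes) >= 1L)
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("sizes must be strictly increasing", call. = FALSE)
  methods <- match.arg(methods, c("naive", "hose", "gnn"),
                       several.ok = TRUE)
  results <- list()
  reports <- list()
  for (seed in seeds) {
    parts <- split_shift_dataset(dataset, test_fraction, seed)
    if (max(sizes) > length(parts$train))
      stop("size ", max(sizes), " exceeds the training pool (",
           length(parts$train), " molecules)", call. = FALSE)
    ord <- with_seed(seed + 10000L,
                     sample.int(length(parts$train)))
    for (size in sizes) {
      train_sub <- parts$train[ord[seq_len(size)]]
      for (method in methods) {
        cfg <- config
        cfg$seed <- config$seed + seed
        if (verbose)
          message(sprintf("seed %d size %d method %s", seed, size, method))
        fit <- .fit_method(method, train_sub, cfg, s_max)
        rep <- .method_metrics(fit, parts$test, train_sub)
        key <- sprintf("%s.%d.%d", method, size, seed)
        reports[[key]] <- rep
        df <- as.data.frame(rep)
        results[[key]] <- data.frame(
          method = method, size = size, seed = seed,
          metric = c("mae", "rmse", "mase", "sigma", "missing_percent",
                     "n_atoms"),
          value = c(df$mae, df$rmse, df$mase, df$sigma,
                    df$missing_percent, df$n_atoms),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, c(results,
                                            list(make.row.names = FALSE))),
                 reports = reports, sizes = sizes, methods = methods,
                 seeds = seeds, nucleus = dataset$nucleus),
            class = "shift_learning_curve")
}

#' Summary matrix of a learning curve
#'
#' Mean of one metric over seeds, methods in rows and training sizes in
#' columns.
#'
#' @param curve A `shift_learning_curve`.
#' @param metric One of `"mae"`, `"rmse"`, `"mase"`, `"sigma"`,
#'   `"missing_percent"`.
#' @param stat Aggregation over seeds (default [mean()]).
#' @return Numeric matrix methods x sizes.
#' @export
curve_matrix <- function(curve, metric = "mae", stat = mean) {
  r <- curve$results[curve$results$metric == metric, ]
  out <- matrix(NA_real_, length(curve$methods), length(curve$sizes),
                dimnames = list(curve$methods, curve$sizes))
  for (m in curve$methods) {
    for (sz in as.character(curve$sizes)) {
      v <- r$value[r$method == m & r$size == as.integer(sz)]
      out[m, sz] <- stat(v)
    }
  }
  out
}

#' @export
print.shift_learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve (%s): sizes %s, %d seed(s)\n", x$nucleus,
              paste(x$sizes, collapse = ", "), length(x$seeds)))
  for (metric in c("mae", "rmse", "mase", "sigma")) {
    cat(sprintf("\n%s%s (mean over seeds):\n", toupper(metric),
                if (metric %in% c("mae", "rmse", "sigma")) " (ppm)" else ""))
    print(round(curve_matrix(x, metric), 3))
  }
  if ("hose" %in% x$methods) {
    cat("\nMissing predictions (%, HOSE):\n")
    print(round(curve_matrix(x, "missing_percent")["hose", , drop = FALSE], 2))
  }
  invisible(x)
}

#' @export
plot.shift_learning_curve <- function(x, metric = "mae", log = "x", ...) {
  mat <- curve_matrix(x, metric)
  graphics::matplot(x$sizes, t(mat), type = "b", pch = 19, lty = 1,
                    log = log, xlab = "training molecules",
                    ylab = paste0(toupper(metric),
                                  if (metric %in% c("mae", "rmse", "sigma"))
                                    " (ppm)" else ""),
                    main = sprintf("%s shift prediction", x$nucleus), ...)
  graphics::legend("topright", legend = rownames(mat), col = seq_len(nrow(mat)),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}

#' Markdown table of a learning curve
#'
#' Renders the familiar benchmark layout: one block per method, rows
#' MAE/RMSE/MASE/sigma (plus missing predictions for HOSE), one column
#' per training size.
#'
#' @param curve A `shift_learning_curve`.
#' @return Character vector of markdown lines.
#' @export
curve_markdown <- function(curve) {
  lines <- c(sprintf("| %s | %s |", "Metric",
                     paste(curve$sizes, collapse = " | ")),
             paste0("|", paste(rep("---|", length(curve$sizes) + 1L),
                               collapse = "")))
  for (m in curve$methods) {
    lines <- c(lines, sprintf("| **%s** | %s |", m,
                              paste(rep("", length(curve$sizes)),
                                    collapse = " | ")))
    for (metric in c("mae", "rmse", "mase", "sigma")) {
      vals <- curve_matrix(curve, metric)[m, ]
      lab <- switch(metric, mae = "MAE (ppm)", rmse = "RMSE (ppm)",
                    mase = "MASE", sigma = "sigma (ppm)")
      lines <- c(lines, sprintf("| %s | %s |", lab,
                                paste(sprintf("%.2f", vals),
                                      collapse = " | ")))
    }
    if (m == "hose") {
      vals <- curve_matrix(curve, "missing_percent")[m, ]
      lines <- c(lines, sprintf("| Missing predictions | %s |",
                                paste(sprintf("%.2f", vals),
                                      collapse = " | ")))
    }
  }
  lines
}

#' Matched-only evaluation
#'
#' Identifies test molecules for which the HOSE lookup cannot predict
#' at least one atom, removes them, and reports metrics for every
#' method on both the full and the reduced test set (models are fitted
#' once on the shared training split).  Whether removal helps either
#' method is an empirical question -- no direction is guaranteed.
#'
#' @param dataset A [shift_dataset()].
#' @param seed Split seed.
#' @param methods Subset of `c("naive", "hose", "gnn")`; `"hose"` is
#'   always included.
#' @param test_fraction Test fraction.
#' @param config [gnn_config()] for the GNN.
#' @param s_max HOSE sphere depth.
#' @return List of class `matched_only_eval` with `full` and `reduced`
#'   (named lists of `shift_metrics`), `removed_ids`, `n_test`.
#' @export
matched_only_evaluation <- function(dataset, seed = 1L,
                                    methods = c("hose", "gnn"),
                                    test_fraction = 0.25,
                                    config = gnn_config(), s_max = 6L) {
  methods <- union("hose", match.arg(methods, c("naive", "hose", "gnn"),
                                     several.ok = TRUE))
  parts <- split_shift_dataset(dataset, test_fraction, seed)
  fits <- lapply(stats::setNames(methods, methods), .fit_method,
                 train = parts$train, config = config, s_max = s_max)
  preds <- lapply(fits, predict, newdata = parts$test)
  hp <- preds[["hose"]]
  bad_ids <- unique(hp$molecule_id[hp$missing_flag])
  keep <- !(molecule_ids(parts$test) %in% bad_ids)
  if (!any(keep))
    stop("matched-only evaluation removed every test molecule",
         call. = FALSE)
  full <- lapply(preds, evaluate_predictions, naive = parts$train)
  reduced <- lapply(preds, function(p) {
    evaluate_predictions(p[!(p$molecule_id %in% bad_ids), , drop = FALSE],
                         naive = parts$train)
  })
  structure(list(full = full, reduced = reduced, removed_ids = bad_ids,
                 n_test = length(parts$test),
                 n_removed = sum(!keep), seed = seed),
            class = "matched_only_eval")
}

#' @export
print.matched_only_eval <- function(x, ...) {
  cat(sprintf("Matched-only evaluation: removed %d of %d test molecules (HOSE missing)\n",
              x$n_removed, x$n_test))
  for (m in names(x$full)) {
    cat(sprintf("  %s full:    ", m)); print(x$full[[m]])
    cat(sprintf("  %s reduced: ", m)); print(x$reduced[[m]])
  }
  invisible(x)
}

#' Hyperparameter search by k-fold cross-validation
#'
#' Molecule-level k-fold cross-validation over a grid of
#' (M, learning rate, weight decay) combinations; selects the
#' configuration minimising mean validation MAE.  Deterministic given
#' the seed.  Folds with zero labeled atoms trigger a refold with a new
#' derived seed, then an error after 3 attempts.
#'
#' @param data Training [shift_dataset()] (never the test split).
#' @param grid data.frame with columns among `M`, `learning_rate`,
#'   `weight_decay` (e.g. from [expand.grid()]); other hyperparameters
#'   come from `base_config`.
#' @param k Number of folds (default 4).
#' @param seed Fold-assignment seed.
#' @param base_config [gnn_config()] supplying the non-searched
#'   hyperparameters.
#' @return List of class `gnn_tuning`: `best_config`, `results`
#'   (per-config mean/sd of fold MAEs), `folds`.
#' @export
tune_gnn <- function(data, grid, k = 4L, seed = 1L,
                     base_config = gnn_config()) {
  stopifnot(inherits(data, "shift_dataset"), nrow(grid) >= 1L,
            length(data) >= k)
  n <- length(data)
  folds <- NULL
  for (attempt in 0:2) {
    f <- with_seed(seed + attempt, sample(rep(seq_len(k), length.out = n)))
    ok <- all(vapply(seq_len(k), function(i) {
      any(vapply(data$records[f == i],
                 function(r) nrow(r$shifts) > 0L, logical(1)))
    }, logical(1)))
    if (ok) { folds <- f; break }
  }
  if (is.null(folds))
    stop("could not build folds with labeled atoms in every fold",
         call. = FALSE)
  res <- data.frame()
  for (g in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in intersect(names(grid), c("M", "learning_rate",
                                        "weight_decay"))) {
      cfg[[nm]] <- if (nm == "M") as.integer(grid[[nm]][g]) else grid[[nm]][g]
    }
    fold_mae <- vapply(seq_len(k), function(i) {
      fit <- nmr_gnn(data[folds != i], config = cfg)
      mean(abs(with(predict(fit, data[folds == i]),
                    predicted_shift_ppm - true_shift_ppm)))
    }, numeric(1))
    row <- grid[g, , drop = FALSE]
    row$mean_mae <- mean(fold_mae)
    row$sd_mae <- stats::sd(fold_mae)
    res <- rbind(res, row)
  }
  best <- which.min(res$mean_mae)
  best_config <- base_config
  for (nm in intersect(names(grid), c("M", "learning_rate", "weight_decay")))
    best_config[[nm]] <- if (nm == "M") as.integer(grid[[nm]][best])
                         else grid[[nm]][best]
  structure(list(best_config = best_config, results = res, folds = folds,
                 k = k, seed = seed),
            class = "gnn_tuning")
}

#' @export
print.gnn_tuning <- function(x, ...) {
  cat(sprintf("%d-fold CV over %d configurations:\n", x$k, nrow(x$results)))
  print(x$results, row.names = FALSE)
  cat("selected:\n")
  print(x$best_config)
  invisible(x)
}

#' Reproduce the published benchmark protocol on a deposited SD file
#'
#' Runs the full published protocol against an nmrshiftdb2 extract:
#' read the SD file, keep one spectrum per compound, optionally
#' restrict to one solvent, then run the learning-curve experiment over
#' the requested training sizes with all three methods.  The deposited
#' extracts (e.g. `nmrshiftdb2withsignals_19f.sd`) must be downloaded
#' separately; this function only needs a path.
#'
#' @param sd_path Path to the deposited SD file.
#' @param nucleus Nucleus label (`"13C"` or `"19F"`).
#' @param sizes Training sizes; values exceeding the available training
#'   pool are clamped to it.
#' @param seeds Split seeds to average over.
#' @param solvent Optional solvent restriction (e.g. `"CDCl3"`).
#' @param config [gnn_config()] for the GNN fits.
#' @param s_max HOSE sphere depth.
#' @param dedup_seed Seed for one-spectrum-per-compound selection.
#' @return A `shift_learning_curve`.
#' @export
reproduce_benchmark <- function(sd_path, nucleus, sizes, seeds = 1:3,
                                solvent = NULL, config = gnn_config(),
                                s_max = 6L, dedup_seed = 1L) {
  data <- read_sd_dataset(sd_path, nucleus)
  data <- deduplicate_spectra(data, seed = dedup_seed)
  if (!is.null(solvent)) data <- filter_by_solvent(data, solvent)
  pool <- length(data) - round(0.25 * length(data))
  sizes <- sort(unique(pmin(as.integer(sizes), pool)))
  learning_curve(data, sizes = sizes, seeds = seeds, config = config,
                 s_max = s_max)
}
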