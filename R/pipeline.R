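#' Per-subject random train/test split
#'
#' Splits each subject's measurement rows into a training part of size
#' `round(train_fraction * N)` and a test remainder, seeded, disjoint and
#' exhaustive; no subject's data crosses the boundary of its own split.
#'
#' @param data A tibble with a `subject_id` column (measurements or
#'   feature rows).
#' @param train_fraction Fraction of each subject's rows used for training
#'   (default 0.75).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test`.
#' @export
split_train_test <- function(data, train_fraction = 0.75, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)")
  }
  if (nrow(data) < 8) stop("need at least 8 measurements to split")
  train_idx <- integer(0)
  for (s in unique(data$subject_id)) {
    rows <- which(data$subject_id == s)
    n_tr <- round(train_fraction * length(rows))
    old <- .Random.seed_guard(child_seed(seed, 401L, as.integer(s)))
    train_idx <- c(train_idx, sort(sample(rows, n_tr)))
    old()
  }
  list(train = data[train_idx, ], test = data[-train_idx, ])
}

#' Column-wise unit-energy normalisation with training gains
#'
#' Computes the unit-energy gain of every feature column on the training
#' block and applies the same gains to the test block.
#'
#' @param train,test Numeric matrices (or data frames) with matching
#'   columns.
#' @return A list with `train`, `test` (scaled matrices) and `gains`.
#' @export
normalize_with_train_gains <- function(train, test = NULL) {
  train <- as.matrix(train)
  gains <- numeric(ncol(train))
  out_tr <- train
  for (j in seq_len(ncol(train))) {
    nc <- suppressWarnings(unit_energy_normalize(train[, j]))
    gains[j] <- nc$gain
    out_tr[, j] <- nc$values
  }
  out_te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    out_te <- sweep(test, 2, gains, `*`)
  }
  list(train = out_tr, test = out_te, gains = gains)
}

#' The ten smoothing labels plus fusion
#'
#' @return Character vector of supported experiment method labels.
#' @export
method_labels <- function() {
  c("O_O", "O_f1", "O_f2", "O_finf", "B1_O", "B2_O", "Binf_O",
    "B1_f1", "B2_f2", "Binf_finf", "fusion")
}

parse_label <- function(label) {
  crit_of <- function(tag) switch(tag, "1" = "L1", "2" = "L2", "inf" = "Linf")
  if (label == "fusion") return(list(mode = "fusion", criterion = NA))
  if (label == "O_O") return(list(mode = "none", criterion = NA))
  m <- regmatches(label, regexec("^O_f(1|2|inf)$", label))[[1]]
  if (length(m)) return(list(mode = "features", criterion = crit_of(m[2])))
  m <- regmatches(label, regexec("^B(1|2|inf)_O$", label))[[1]]
  if (length(m)) return(list(mode = "reference", criterion = crit_of(m[2])))
  m <- regmatches(label, regexec("^B(1|2|inf)_f(1|2|inf)$", label))[[1]]
  if (length(m) && m[2] == m[3]) {
    return(list(mode = "both", criterion = crit_of(m[2])))
  }
  stop("unknown method label: ", label)
}

#' Run the per-subject estimation experiment
#'
#' For each subject: split into train/test, normalise features with the
#' training gains, apply each requested smoothing label to the training
#' block (features, reference glucose, both, neither, or the fusion rule),
#' select features by random-forest importance, train the regressor,
#' predict the test block and score it. Test features are normalised but
#' never smoothed. Pooled metrics are computed on the concatenated
#' per-subject test predictions.
#'
#' @param feature_tbl A feature table from [extract_features()]
#'   (columns `subject_id`, `measurement_id`, `glucose_ref` and the
#'   feature columns).
#' @param labels Method labels to run, a subset of [method_labels()].
#' @param model Base regressor for the non-fusion labels
#'   (`"rf"`, `"svr"`, `"gpr"`).
#' @param train_fraction Per-subject training fraction (default 0.75).
#' @param cfg A [fusion_config()] (also supplies `n_selected_features`,
#'   `rf_trees` and the seed for the non-fusion labels).
#' @return An object of class `glucose_experiment`: list with
#'   `predictions` (tibble: subject, method, ref, est), `per_subject` and
#'   `pooled` metric tibbles (each with a Clarke zone-A percentage).
#' @export
run_experiment <- function(feature_tbl, labels = c("O_O", "O_f2", "fusion"),
                           model = "rf", train_fraction = 0.75,
                           cfg = fusion_config()) {
  stopifnot(all(labels %in% method_labels()))
  meta_cols <- c("subject_id", "measurement_id", "glucose_ref")
  fcols <- setdiff(names(feature_tbl), meta_cols)
  preds <- list()
  for (s in unique(feature_tbl$subject_id)) {
    sub <- feature_tbl[feature_tbl$subject_id == s, ]
    sp <- split_train_test(sub, train_fraction, child_seed(cfg$seed, 3L))
    g_tr <- sp$train$glucose_ref
    g_te <- sp$test$glucose_ref
    nz <- normalize_with_train_gains(sp$train[fcols], sp$test[fcols])
    for (lab in labels) {
      plan <- parse_label(lab)
      if (plan$mode == "fusion") {
        fm <- build_fusion_model(nz$train, g_tr, cfg)
        est <- predict(fm, nz$test)
      } else {
        f_tr <- nz$train
        y_tr <- g_tr
        if (plan$mode %in% c("features", "both")) {
          f_tr <- smooth_features(f_tr, g_tr, plan$criterion)
        }
        if (plan$mode %in% c("reference", "both")) {
          y_tr <- smooth_reference(nz$train, g_tr, plan$criterion)
        }
        k <- min(cfg$n_selected_features, ncol(f_tr))
        sel <- select_features_rf(f_tr, y_tr, k = k,
                                  seed = child_seed(cfg$seed, 41L),
                                  rf_trees = cfg$rf_trees)
        fit <- train_base_model(f_tr[, sel, drop = FALSE], y_tr, model,
                                seed = child_seed(cfg$seed, 43L),
                                rf_trees = cfg$rf_trees)
        est <- predict(fit, nz$test[, sel, drop = FALSE])
      }
      preds[[length(preds) + 1L]] <- tibble::tibble(
        subject_id = s, method = lab, ref = g_te, est = est
      )
    }
  }
  predictions <- dplyr::bind_rows(preds)
  score <- function(d) {
    dplyr::bind_cols(
      regression_metrics(d$ref, d$est),
      tibble::tibble(zone_a_pct = clarke_percentages(d$ref, d$est)$pct[1])
    )
  }
  per_subject <- predictions |>
    dplyr::group_by(.data$subject_id, .data$method) |>
    dplyr::group_modify(~ score(.x)) |>
    dplyr::ungroup()
  pooled <- predictions |>
    dplyr::group_by(.data$method) |>
    dplyr::group_modify(~ score(.x)) |>
    dplyr::ungroup()
  structure(list(predictions = predictions, per_subject = per_subject,
                 pooled = pooled),
            class = "glucose_experiment")
}

#' @export
print.glucose_experiment <- function(x, ...) {
  cat("<glucose_experiment>\n")
  print(x$pooled)
  invisible(x)
}

#' Pooled metric table of an experiment
#'
#' @param x A `glucose_experiment`.
#' @param ... Unused.
#' @return The pooled metrics tibble (one row per method label).
#' @exportS3Method generics::tidy
tidy.glucose_experiment <- function(x, ...) x$pooled

#' Plot an experiment's predictions on the Clarke error grid
#'
#' @param object A `glucose_experiment`.
#' @param method Which method label to plot (default the first present).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.glucose_experiment <- function(object, method = NULL, ...) {
  d <- object$predictions
  if (is.null(method)) method <- d$method[1]
  d <- d[d$method == method, ]
  plot_clarke(d$ref, d$est) +
    ggplot2::ggtitle(paste("Clarke error grid -", method))
}
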