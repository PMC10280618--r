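#' Fusion configuration
#'
#' @param epsilon Accumulate-probability threshold in (0, 1); a region is
#'   closed as soon as one criterion's running fraction of per-point wins
#'   since the last reset exceeds it (default 0.6).
#' @param min_region_points Minimum points accumulated before the fractions
#'   are evaluated (default 3); keeps the first point since a reset from
#'   trivially firing at fraction 1.
#' @param tie_priority Order in which criteria win ties
#'   (default `c("L1", "L2", "Linf")`).
#' @param n_selected_features Number of features kept by random-forest
#'   importance ranking (default 25).
#' @param rf_trees Trees per random forest (default 100).
#' @param seed Integer seed.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(epsilon = 0.6, min_region_points = 3L,
                          tie_priority = c("L1", "L2", "Linf"),
                          n_selected_features = 25L, rf_trees = 100L,
                          seed = 1L) {
  if (epsilon <= 0 || epsilon >= 1) stop("epsilon must be in (0, 1)")
  stopifnot(min_region_points >= 1,
            setequal(tie_priority, c("L1", "L2", "Linf")))
  structure(
    list(epsilon = epsilon, min_region_points = as.integer(min_region_points),
         tie_priority = tie_priority,
         n_selected_features = as.integer(n_selected_features),
         rf_trees = as.integer(rf_trees), seed = as.integer(seed)),
    class = "fusion_config"
  )
}

#' Select features by random-forest importance
#'
#' Fits a seeded random forest of the glucose target on all feature columns
#' and keeps the `k` columns of largest impurity importance (ties broken by
#' lower column index).
#'
#' @param features Numeric matrix or data frame of feature columns.
#' @param glucose Numeric target vector.
#' @param k Number of features to keep (default 25).
#' @param seed Integer seed.
#' @param rf_trees Number of trees (default 100).
#' @return Integer vector of `k` column indices, ascending.
#' @export
select_features_rf <- function(features, glucose, k = 25L, seed = 1L,
                               rf_trees = 100L) {
  features <- as.matrix(features)
  if (ncol(features) < k) {
    stop("cannot select ", k, " features from ", ncol(features), " columns")
  }
  if (nrow(features) < 5) stop("need at least 5 training rows")
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  rf <- suppressWarnings(
    randomForest::randomForest(x = features, y = glucose, ntree = rf_trees)
  )
  imp <- drop(randomForest::importance(rf)[, 1])
  sort(order(-imp, seq_along(imp))[seq_len(k)])
}

#' Train a base regressor
#'
#' @param features Numeric matrix of predictor columns.
#' @param glucose Numeric target (mmol/L).
#' @param kind `"rf"` (random forest, the kind fused), `"svr"` (support
#'   vector regression) or `"gpr"` (Gaussian process regression).
#' @param seed Integer seed.
#' @param rf_trees Trees for the random forest.
#' @return A `base_model` object with a `predict()` method returning mmol/L.
#' @export
train_base_model <- function(features, glucose, kind = c("rf", "svr", "gpr"),
                             seed = 1L, rf_trees = 100L) {
  kind <- match.arg(kind)
  features <- as.matrix(features)
  if (nrow(features) < 5) stop("need at least 5 training rows")
  if (stats::sd(glucose) == 0) {
    return(structure(list(kind = "constant", value = glucose[1]),
                     class = "base_model"))
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  fit <- switch(kind,
    rf = suppressWarnings(
      randomForest::randomForest(x = features, y = glucose, ntree = rf_trees)),
    svr = e1071::svm(x = features, y = glucose),
    gpr = kernlab::gausspr(x = features, y = glucose)
  )
  structure(list(kind = kind, fit = fit), class = "base_model")
}

#' @export
predict.base_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "constant") {
    return(rep(object$value, nrow(newdata)))
  }
  if (object$kind == "gpr") {
    drop(kernlab::predict(object$fit, newdata))
  } else {
    unname(drop(stats::predict(object$fit, newdata)))
  }
}

#' Split a training set for fusion
#'
#' Two thirds (rounded) become the new training set and the remainder the
#' validation set; seeded, disjoint and exhaustive. Applied after the
#' initial 75/25 train/test split this leaves 50% / 25% / 25% of all data
#' in new-train / validation / test.
#'
#' @param n Number of training rows (or a data frame, whose row count is
#'   used).
#' @param seed Integer seed.
#' @return A list with integer index vectors `new_train` and `validation`.
#' @export
split_for_fusion <- function(n, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  if (n < 9) stop("need at least 9 training rows for the fusion split")
  n_new <- round(2 * n / 3)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  idx <- sample.int(n, n_new)
  list(new_train = sort(idx), validation = setdiff(seq_len(n), idx))
}

#' Partition the sorted validation glucose axis into criterion regions
#'
#' Walks the per-point winning criteria in ascending-glucose order keeping
#' per-criterion win counts since the last reset. Once at least
#' `min_region_points` points have accumulated, the running fractions are
#' evaluated; if the largest exceeds `epsilon`, a region is closed at that
#' point (boundary = midpoint between this and the next glucose value),
#' labelled with the maximal-fraction criterion, and the counts reset.
#' Any tail points form a final region labelled with their plurality
#' criterion (ties broken by `tie_priority`).
#'
#' @param sorted_glucose Ascending validation glucose values.
#' @param winners Character vector of per-point winning criteria
#'   (`"L1"`, `"L2"`, `"Linf"`), same length.
#' @param cfg A [fusion_config()].
#' @return A list with `boundaries` (ascending numeric, possibly empty) and
#'   `region_methods` (character, `length(boundaries) + 1`).
#' @export
partition_regions <- function(sorted_glucose, winners, cfg = fusion_config()) {
  n <- length(winners)
  stopifnot(n >= 1, length(sorted_glucose) == n,
            !is.unsorted(sorted_glucose),
            all(winners %in% c("L1", "L2", "Linf")))
  counts <- c(L1 = 0, L2 = 0, Linf = 0)
  since <- 0L
  boundaries <- numeric(0)
  methods <- character(0)
  plurality <- function(counts) {
    mx <- max(counts)
    for (m in cfg$tie_priority) if (counts[m] == mx) return(m)
  }
  for (i in seq_len(n)) {
    counts[winners[i]] <- counts[winners[i]] + 1
    since <- since + 1L
    if (since >= cfg$min_region_points) {
      frac <- counts / since
      if (max(frac) > cfg$epsilon) {
        methods <- c(methods, plurality(counts))
        if (i < n) {
          boundaries <- c(boundaries,
                          (sorted_glucose[i] + sorted_glucose[i + 1L]) / 2)
        }
        counts[] <- 0
        since <- 0L
      }
    }
  }
  # tail points since the last reset form the final region; if the walk
  # closed a region exactly at the last point there is no tail to add
  if (since > 0L) methods <- c(methods, plurality(counts))
  stopifnot(length(methods) == length(boundaries) + 1L)
  list(boundaries = boundaries, region_methods = methods)
}

#' Build a fused glucose estimator
#'
#' Implements the fusion rule: the training set is split 2/3 new-train,
#' 1/3 validation; for each smoothing criterion the new-train features are
#' smoothed under it, features selected by random-forest importance, a
#' random forest trained, and validation absolute errors computed; errors
#' are sorted by ascending validation glucose; each point's winning
#' criterion is the argmin of the three errors (ties by
#' `cfg$tie_priority`); [partition_regions()] turns the winner sequence
#' into glucose regions.
#'
#' @param features Numeric matrix of normalised training features
#'   (rows = measurements).
#' @param glucose Training reference glucose (mmol/L).
#' @param cfg A [fusion_config()].
#' @return A `fusion_model` with per-criterion regressors and selected
#'   columns, region `boundaries` and `region_methods`.
#' @export
build_fusion_model <- function(features, glucose, cfg = fusion_config()) {
  features <- as.matrix(features)
  if (nrow(features) < 12) stop("need at least 12 training rows for fusion")
  crits <- c("L1", "L2", "Linf")
  sp <- split_for_fusion(nrow(features), child_seed(cfg$seed, 11L))
  f_tr <- features[sp$new_train, , drop = FALSE]
  g_tr <- glucose[sp$new_train]
  f_va <- features[sp$validation, , drop = FALSE]
  g_va <- glucose[sp$validation]

  models <- list(); selected <- list(); errors <- list()
  for (m in crits) {
    f_sm <- smooth_features(f_tr, g_tr, m)
    k <- min(cfg$n_selected_features, ncol(f_sm))
    sel <- select_features_rf(f_sm, g_tr, k = k,
                              seed = child_seed(cfg$seed, 23L, match(m, crits)),
                              rf_trees = cfg$rf_trees)
    fit <- train_base_model(f_sm[, sel, drop = FALSE], g_tr, "rf",
                            seed = child_seed(cfg$seed, 31L, match(m, crits)),
                            rf_trees = cfg$rf_trees)
    est <- predict(fit, f_va[, sel, drop = FALSE])
    models[[m]] <- fit
    selected[[m]] <- sel
    errors[[m]] <- abs(est - g_va)
  }
  ord <- order(g_va)
  e_mat <- cbind(L1 = errors$L1[ord], L2 = errors$L2[ord],
                 Linf = errors$Linf[ord])
  prio <- match(crits, cfg$tie_priority)
  winners <- apply(e_mat, 1, function(e) {
    cand <- which(e == min(e))
    crits[cand[order(prio[cand])][1]]
  })
  part <- partition_regions(g_va[ord], winners, cfg)
  structure(
    list(models = models, selected_features = selected,
         boundaries = part$boundaries, region_methods = part$region_methods,
         config = cfg,
         validation = tibble::tibble(sorted_glucose = g_va[ord],
                                     e1 = e_mat[, "L1"], e2 = e_mat[, "L2"],
                                     einf = e_mat[, "Linf"],
                                     winner = winners)),
    class = "fusion_model"
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  cat("<fusion_model>", length(x$region_methods), "region(s):",
      paste(x$region_methods, collapse = " | "), "\n")
  if (length(x$boundaries)) {
    cat("  boundaries (mmol/L):",
        paste(signif(x$boundaries, 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tidy the region table of a fusion model
#'
#' @param x A `fusion_model`.
#' @param ... Unused.
#' @return A tibble with one row per region: `region`, `lower`, `upper`,
#'   `method`.
#' @exportS3Method generics::tidy
tidy.fusion_model <- function(x, ...) {
  b <- x$boundaries
  tibble::tibble(
    region = seq_along(x$region_methods),
    lower = c(-Inf, b),
    upper = c(b, Inf),
    method = x$region_methods
  )
}

#' Predict glucose with a fused model
#'
#' Each criterion's random forest produces an estimate from its selected
#' feature columns; the mean of the three estimates locates the glucose
#' region; the returned value is the estimate of that region's criterion.
#'
#' @param object A `fusion_model`.
#' @param newdata Numeric matrix of normalised feature rows (full feature
#'   width; each criterion picks its own columns).
#' @param ... Unused.
#' @return Numeric vector of fused glucose estimates (mmol/L).
#' @export
predict.fusion_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  need <- max(unlist(object$selected_features))
  if (ncol(newdata) < need) {
    stop("newdata has ", ncol(newdata), " columns but the model selects up to ",
         "column ", need)
  }
  est <- vapply(c("L1", "L2", "Linf"), function(m) {
    predict(object$models[[m]],
            newdata[, object$selected_features[[m]], drop = FALSE])
  }, numeric(nrow(newdata)))
  if (nrow(newdata) == 1) est <- matrix(est, nrow = 1,
                                        dimnames = list(NULL, c("L1", "L2", "Linf")))
  locator <- rowMeans(est)
  region <- findInterval(locator, object$boundaries) + 1L
  vapply(seq_along(locator), function(i) {
    est[i, object$region_methods[region[i]]]
  }, numeric(1))
}
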