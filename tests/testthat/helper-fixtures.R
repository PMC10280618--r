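# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a noiseless single-measurement recording: exact beat round-trips
clean_measurement <- function() {
  fixture("clean_measurement", function() {
    cfg <- synth_config(n_subjects = 1, measurements_per_subject = 1,
                        duration_s = 40, noise_sd = 0, drift_amp = 0,
                        seed = 303L)
    generate_dataset(cfg)
  })
}

# a small noisy cohort, denoised, with its feature table
small_cohort_features <- function() {
  fixture("small_cohort_features", function() {
    cfg <- synth_config(n_subjects = 1, measurements_per_subject = 12,
                        duration_s = 35, seed = 404L)
    d <- denoise_measurements(generate_dataset(cfg))
    list(measurements = d, features = suppressWarnings(extract_features(d)))
  })
}

# a feature table with planted noisy-cubic glucose coupling (no signal
# chain), for fast pipeline-level tests
planted_feature_table <- function(seed = 1L, n = 48L, n_informative = 24L,
                                  n_junk = 6L, noise_sd = 0.8) {
  set.seed(seed)
  g <- sort(runif(n, 4, 12))
  ncol_total <- n_informative + n_junk
  X <- sapply(seq_len(ncol_total), function(j) {
    if (j <= n_informative) {
      b <- runif(3, -1, 1)
      f <- b[1] * g + b[2] * (g / 10)^2 * 10 + b[3] * (g / 10)^3 * 10
      f <- (f - mean(f)) / stats::sd(f)
      f + rnorm(n, 0, noise_sd)
    } else {
      rnorm(n)
    }
  })
  colnames(X) <- sprintf("f%02d", seq_len(ncol_total))
  dplyr::bind_cols(
    tibble::tibble(subject_id = 1, measurement_id = seq_len(n),
                   glucose_ref = g),
    tibble::as_tibble(as.data.frame(X))
  )
}

# brute-force L1 oracle: an optimal least-absolute-deviation cubic
# interpolates 4 points (generic position); enumerate all 4-subsets
oracle_l1_objective <- function(x, y) {
  X <- design_matrix(x)
  best <- Inf
  for (S in utils::combn(length(x), 4, simplify = FALSE)) {
    a <- tryCatch(solve(X[S, ], y[S]), error = function(e) NULL)
    if (!is.null(a)) best <- min(best, sum(abs(X %*% a - y)))
  }
  best
}

# equioscillation oracle for the minimax cubic: on a sorted abscissa the
# optimum attains +/- eps alternately on a reference of 5 points
oracle_linf_objective <- function(x, y) {
  stopifnot(!is.unsorted(x))
  X <- design_matrix(x)
  best <- Inf
  for (S in utils::combn(length(x), 5, simplify = FALSE)) {
    for (sgn in list(c(1, -1, 1, -1, 1), c(-1, 1, -1, 1, -1))) {
      M <- cbind(X[S, ], -sgn)
      sol <- tryCatch(solve(M, y[S]), error = function(e) NULL)
      if (is.null(sol)) next
      eps <- sol[5]
      if (eps < 0) next
      if (max(abs(X %*% sol[1:4] - y)) <= eps + 1e-9) best <- min(best, eps)
    }
  }
  best
}

# a hand-built fused model around constant-output base regressors, for
# exercising the region lookup rule in isolation
constant_fusion_model <- function(estimates, boundaries, region_methods) {
  models <- lapply(estimates, function(v) {
    structure(list(kind = "constant", value = v), class = "base_model")
  })
  names(models) <- c("L1", "L2", "Linf")
  structure(
    list(models = models,
         selected_features = list(L1 = 1:2, L2 = 1:2, Linf = 1:2),
         boundaries = boundaries, region_methods = region_methods,
         config = fusion_config()),
    class = "fusion_model"
  )
}
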