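#' Regression accuracy metrics for glucose estimation
#'
#' Pearson correlation R, mean absolute error, the sample SD of the
#' absolute errors, root mean squared error, and the mean absolute relative
#' deviation MARD = mean(|est - ref| / ref), the standard accuracy figure
#' for glucose monitors.
#'
#' @param ref Reference glucose values (mmol/L), all positive.
#' @param est Estimated glucose values (mmol/L), same length.
#' @return A one-row tibble: `r`, `mae`, `sd_ae`, `rmse`, `mard`.
#' @examples
#' regression_metrics(c(5, 10), c(4.5, 11))
#' @export
regression_metrics <- function(ref, est) {
  stopifnot(length(ref) == length(est), length(ref) >= 2,
            all(is.finite(ref)), all(is.finite(est)))
  if (any(ref <= 0)) stop("reference glucose must be positive for MARD")
  ae <- abs(est - ref)
  r <- if (stats::sd(ref) == 0 || stats::sd(est) == 0) {
    warning("constant input: correlation undefined, reporting r = 0")
    0
  } else {
    stats::cor(ref, est)
  }
  tibble::tibble(
    r = r,
    mae = mean(ae),
    sd_ae = stats::sd(ae),
    rmse = sqrt(mean((est - ref)^2)),
    mard = mean(ae / ref)
  )
}

MGDL_PER_MMOL <- 18.018

#' Clarke error grid zone of one or more (reference, estimate) pairs
#'
#' Values are converted from mmol/L to mg/dL (factor 18.018) and classified
#' by the original 1987 zone inequalities: A when the estimate is within
#' 20% of the reference or both read below 70 mg/dL; E for opposite-extreme
#' errors (hypo read as hyper or vice versa); C for overcorrection wedges;
#' D for dangerous failures to detect; B otherwise.
#'
#' @param ref,est Positive glucose values in mmol/L (vectorised).
#' @return Character vector of zones `"A"`..`"E"`.
#' @export
clarke_zone <- function(ref, est) {
  stopifnot(length(ref) == length(est))
  if (any(ref <= 0) || any(est <= 0)) stop("glucose values must be positive")
  y <- ref * MGDL_PER_MMOL
  yp <- est * MGDL_PER_MMOL
  vapply(seq_along(y), function(i) clarke_zone1(y[i], yp[i]), character(1))
}

clarke_zone1 <- function(y, yp) {
  if ((y <= 70 && yp <= 70) || (yp >= 0.8 * y && yp <= 1.2 * y)) return("A")
  if ((y >= 180 && yp <= 70) || (y <= 70 && yp >= 180)) return("E")
  if ((y >= 70 && y <= 290 && yp >= y + 110) ||
      (y >= 130 && y <= 180 && yp <= (7 / 5) * y - 182)) return("C")
  if ((y >= 240 && yp >= 70 && yp <= 180) ||
      (y <= 175 / 3 && yp >= 70 && yp <= 180) ||
      (y >= 175 / 3 && y <= 70 && yp >= (6 / 5) * y)) return("D")
  "B"
}

#' Clarke error grid zone counts and percentages
#'
#' @param ref,est Positive glucose values in mmol/L.
#' @return A tibble with one row per zone A..E: `zone`, `count`, `pct`
#'   (percentages sum to 100).
#' @export
clarke_percentages <- function(ref, est) {
  stopifnot(length(ref) >= 1)
  z <- factor(clarke_zone(ref, est), levels = c("A", "B", "C", "D", "E"))
  counts <- as.integer(table(z))
  tibble::tibble(zone = levels(z), count = counts,
                 pct = 100 * counts / length(ref))
}

#' Plot predictions on the Clarke error grid
#'
#' @param ref,est Positive glucose values in mmol/L.
#' @return A ggplot object with the zone boundary segments (drawn in
#'   mg/dL) and the prediction scatter.
#' @export
plot_clarke <- function(ref, est) {
  pts <- tibble::tibble(ref = ref * MGDL_PER_MMOL,
                        est = est * MGDL_PER_MMOL,
                        zone = clarke_zone(ref, est))
  seg <- tibble::tribble(
    ~x, ~y, ~xend, ~yend,
    0, 0, 400, 400,                 # identity
    0, 70, 175 / 3, 70,             # D lower-left top
    175 / 3, 70, 70, 84,            # D wedge
    70, 84, 70, 400 * 1.2,          # A upper 20% line start
    0, 180, 70, 180,                # E upper-left
    240, 70, 240, 180,              # D right box left
    240, 180, 400, 180,             # D right box top
    130, 0, 180, 70,                # C lower wedge
    70, 180, 290, 400,              # C upper wedge (est = ref + 110)
    70, 56, 400, 320                # A lower 20% line
  )
  ggplot2::ggplot(pts, ggplot2::aes(x = ref, y = est)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = x, y = y, xend = xend, yend = yend),
                          inherit.aes = FALSE, linetype = "dashed",
                          colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = zone), size = 2) +
    ggplot2::coord_cartesian(xlim = c(0, 400), ylim = c(0, 400)) +
    ggplot2::labs(x = "Reference glucose (mg/dL)",
                  y = "Estimated glucose (mg/dL)",
                  title = "Clarke error grid") +
    ggplot2::theme_minimal()
}
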