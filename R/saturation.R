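#' Region-of-interest saturation curve
#'
#' The saturation fraction at time t is the share of vessel pixels inside the
#' ROI that have received at least one microbubble localization by t. Full
#' saturation occurs when every vessel pixel in the ROI has been hit. The
#' curve is normalized by its maximum over the analyzed window, so it ends at
#' 1 (skipped, with a flag, if no pixel is ever hit). Time starts at the
#' first analyzed frame: frame k is reported at t = k / frame_rate.
#'
#' @param localizations Tibble with `frame`, `row`, `col` on the same grid as
#'   `vessel_mask` (typically the upsampled grid from [ulm_localize()]).
#' @param roi Integer vector `c(row0, col0)`: top-left corner of the ROI;
#'   with `roi_size` it defines the window (default 25 x 25 pixels).
#' @param vessel_mask Logical matrix on the full grid: TRUE for pixels inside
#'   the vessel.
#' @param frame_rate Hz; from the table's attributes if absent.
#' @param n_frames Number of frames analyzed (default: 3000 or the largest
#'   frame present, whichever is smaller).
#' @param roi_size ROI side length in pixels.
#' @return A tibble of class `saturation_curve`: `time_s`, `fraction`
#'   (normalized), `raw_fraction`; attributes `n_vessel_px`, `normalized`,
#'   `frame_rate`.
#' @export
saturation_curve <- function(localizations, roi, vessel_mask,
                             frame_rate = NULL, n_frames = NULL,
                             roi_size = 25) {
  frame_rate <- frame_rate %||% attr(localizations, "frame_rate")
  stopifnot(!is.null(frame_rate))
  rows <- roi[1]:(roi[1] + roi_size - 1)
  cols <- roi[2]:(roi[2] + roi_size - 1)
  rows <- rows[rows >= 1 & rows <= nrow(vessel_mask)]
  cols <- cols[cols >= 1 & cols <= ncol(vessel_mask)]
  sub <- vessel_mask[rows, cols, drop = FALSE]
  n_px <- sum(sub)
  if (n_px == 0) {
    stop("saturation_curve: no vessel pixels inside the ROI", call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- min(3000, max(localizations$frame, 1))
  }
  loc <- localizations[localizations$frame <= n_frames, ]
  r <- round(loc$row); c <- round(loc$col)
  inside <- r >= min(rows) & r <= max(rows) & c >= min(cols) & c <= max(cols)
  loc <- loc[inside, ]; r <- r[inside]; c <- c[inside]
  in_vessel <- vessel_mask[cbind(r, c)]
  loc <- loc[in_vessel, ]; r <- r[in_vessel]; c <- c[in_vessel]

  hits_per_frame <- integer(n_frames)
  if (nrow(loc) > 0) {
    px <- paste(r, c)
    first_hit <- tapply(loc$frame, px, min)
    tab <- table(factor(first_hit, levels = seq_len(n_frames)))
    hits_per_frame <- as.integer(tab)
  }
  raw <- cumsum(hits_per_frame) / n_px
  peak <- max(raw)
  normalized <- peak > 0
  frac <- if (normalized) raw / peak else raw
  structure(tibble::tibble(
    time_s = seq_len(n_frames) / frame_rate,
    fraction = frac,
    raw_fraction = raw
  ), n_vessel_px = n_px, normalized = normalized, frame_rate = frame_rate,
     class = c("saturation_curve", class(tibble::tibble())))
}

#' Fit the exponential saturation model and extract tau
#'
#' Least-squares fit of S(t) = 1 - exp(-t / tau) to a normalized saturation
#' curve. tau is the time at which the fitted curve reaches 63%
#' (1 - 1/e) of its final value. Fits with R^2 below 0.98 are flagged with a
#' warning.
#'
#' @param curve A [saturation_curve()] (or tibble with `time_s`, `fraction`).
#' @return An object of class `tau_fit`: fields `tau` (s), `r_squared`,
#'   `flagged`, `n`, and `data` (observed plus fitted values). Supports
#'   [generics::tidy()], [generics::glance()] and `autoplot()`.
#' @examples
#' t <- seq(0.004, 12, by = 0.004)
#' fit <- fit_exponential(tibble::tibble(time_s = t,
#'                                       fraction = 1 - exp(-t / 2.15)))
#' fit$tau
#' @export
fit_exponential <- function(curve) {
  t <- curve$time_s
  y <- curve$fraction
  if (length(t) < 10) {
    stop("fit_exponential: need at least 10 time points", call. = FALSE)
  }
  if (max(y) <= 0 || stats::cor(t, y) <= 0) {
    stop("fit_exponential: degenerate (flat or non-monotone) curve",
         call. = FALSE)
  }
  sse <- function(log_tau) sum((y - (1 - exp(-t / exp(log_tau))))^2)
  opt <- stats::optimize(sse, c(log(min(diff(t)) / 10), log(100 * max(t))))
  tau <- exp(opt$minimum)
  fitted <- 1 - exp(-t / tau)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  flagged <- r2 < 0.98
  if (flagged) {
    warning(sprintf("saturation fit flagged: R^2 = %.3f < 0.98", r2),
            call. = FALSE)
  }
  structure(list(tau = tau, r_squared = r2, flagged = flagged,
                 n = length(t),
                 data = tibble::tibble(time_s = t, fraction = y,
                                       fitted = fitted)),
            class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat(sprintf("<tau_fit> tau = %.3f s, R^2 = %.4f%s (n = %d)\n", x$tau,
              x$r_squared, if (x$flagged) " [flagged]" else "", x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.tau_fit <- function(x, ...) {
  tibble::tibble(term = "tau", estimate = x$tau, unit = "s")
}

#' @export
glance.tau_fit <- function(x, ...) {
  tibble::tibble(tau = x$tau, r_squared = x$r_squared, flagged = x$flagged,
                 n = x$n)
}

#' Percent increase of a branch tau over the main-channel tau
#'
#' @param tau_branch,tau_main Saturation time constants, s (`tau_main` > 0).
#' @return (tau_branch - tau_main) / tau_main x 100, in percent.
#' @examples
#' percent_increase(2.09, 1.21)  # ~72.7
#' @export
percent_increase <- function(tau_branch, tau_main) {
  if (any(!is.finite(tau_main)) || any(tau_main <= 0)) {
    stop("percent_increase: tau_main must be positive", call. = FALSE)
  }
  (tau_branch - tau_main) / tau_main * 100
}

#' Two-sample comparison of tau replicates
#'
#' Unpaired two-tailed two-sample t-test (pooled variance) between two groups
#' of replicate tau estimates, with per-group mean and SD. P values below
#' 0.05 are considered significant.
#'
#' @param group_a,group_b Numeric vectors of tau replicates (>= 2 each).
#' @param alpha Significance threshold.
#' @return A one-row tibble: group means, SDs, sizes, `statistic`, `df`,
#'   `p_value`, `significant`.
#' @export
compare_taus <- function(group_a, group_b, alpha = 0.05) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("compare_taus: need at least 2 replicates per group", call. = FALSE)
  }
  tt <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(
    n_a = length(group_a), mean_a = mean(group_a), sd_a = stats::sd(group_a),
    n_b = length(group_b), mean_b = mean(group_b), sd_b = stats::sd(group_b),
    statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value < alpha
  )
}

#' Place a 25 x 25 ROI just downstream of a junction on a daughter segment
#'
#' @param network A [channel_network()].
#' @param segment_id Daughter segment id.
#' @param origin,pixel_size_mm Grid metadata of the localization grid.
#' @param roi_size ROI side, pixels.
#' @param gap_px Pixels between the junction and the ROI edge.
#' @return Integer `c(row0, col0)` top-left corner for [saturation_curve()].
#' @export
roi_after_junction <- function(network, segment_id, origin, pixel_size_mm,
                               roi_size = 25, gap_px = 2) {
  seg <- network$segments[network$segments$id == segment_id, ]
  if (nrow(seg) != 1) {
    stop("roi_after_junction: unknown segment '", segment_id, "'",
         call. = FALSE)
  }
  len <- sqrt((seg$x1 - seg$x0)^2 + (seg$z1 - seg$z0)^2)
  ax <- (seg$x1 - seg$x0) / len; az <- (seg$z1 - seg$z0) / len
  d <- min((gap_px + roi_size / 2) * pixel_size_mm, len / 2)
  cx <- seg$x0 + d * ax; cz <- seg$z0 + d * az
  row0 <- round((cz - origin[2]) / pixel_size_mm) + 1 - floor(roi_size / 2)
  col0 <- round((cx - origin[1]) / pixel_size_mm) + 1 - floor(roi_size / 2)
  c(max(1L, as.integer(row0)), max(1L, as.integer(col0)))
}

#' Write a saturation curve and its fit as CSV
#'
#' @param curve A [saturation_curve()].
#' @param fit Optional [fit_exponential()] result for the same curve.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_saturation <- function(curve, path, fit = NULL) {
  out <- tibble::as_tibble(curve)
  if (!is.null(fit)) out$fitted_fraction <- fit$data$fitted
  readr::write_csv(out, path)
  invisible(path)
}
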