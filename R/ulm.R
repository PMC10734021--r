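#' Bicubic frame upsampling
#'
#' Deterministic separable bicubic interpolation (Catmull-Rom / Keys kernel,
#' a = -0.5) with the align-centres convention: output pixel `i` samples
#' input coordinate `(i - 0.5) / factor + 0.5`, edges replicated. The
#' upsampler sits behind this interface so a learned super-resolution model
#' could be substituted; bicubic preserves the grid geometry exactly and
#' reproduces constant regions.
#'
#' @param frame A numeric matrix.
#' @param factor Integer upsampling factor (>= 1); 2 doubles each dimension.
#' @return A `nrow(frame) * factor` x `ncol(frame) * factor` matrix.
#' @export
upsample_frame <- function(frame, factor = 2L) {
  if (!is.numeric(factor) || factor < 1 || factor != round(factor)) {
    stop("upsample_frame: factor must be an integer >= 1", call. = FALSE)
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(frame)
  wr <- bicubic_weights(nrow(frame), factor)
  wc <- bicubic_weights(ncol(frame), factor)
  wr %*% frame %*% t(wc)
}

# Keys cubic convolution kernel, a = -0.5 (Catmull-Rom).
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# (n * factor) x n sparse-pattern weight matrix for 1-D cubic upsampling.
bicubic_weights <- function(n, factor) {
  m <- n * factor
  w <- matrix(0, m, n)
  for (i in seq_len(m)) {
    p <- (i - 0.5) / factor + 0.5
    base <- floor(p)
    taps <- (base - 1):(base + 2)
    k <- cubic_kernel(p - taps)
    taps <- pmin(pmax(taps, 1), n)     # replicate edges
    for (t in seq_along(taps)) w[i, taps[t]] <- w[i, taps[t]] + k[t]
  }
  w
}

#' @rdname upsample_frame
#' @param stack A [frame_stack()].
#' @return `upsample_stack()` returns a [frame_stack()] on the finer grid
#'   (pixel size divided by `factor`, origin shifted to the first fine-pixel
#'   centre).
#' @export
upsample_stack <- function(stack, factor = 2L) {
  factor <- as.integer(factor)
  d <- dim(stack)
  if (factor == 1L) return(stack)
  wr <- bicubic_weights(d[1], factor)
  wc <- t(bicubic_weights(d[2], factor))
  out <- array(0, dim = c(d[1] * factor, d[2] * factor, d[3]))
  for (f in seq_len(d[3])) out[, , f] <- wr %*% stack[, , f] %*% wc
  ps <- attr(stack, "pixel_size_mm")
  origin <- attr(stack, "origin") + ((0.5 / factor + 0.5) - 1) * ps
  frame_stack(out, attr(stack, "frame_rate"), ps / factor, origin)
}

#' SVD clutter filter
#'
#' Reshapes the stack into its Casorati matrix (pixels x frames), removes the
#' `n_remove` largest singular components, and reshapes back. Low-rank
#' components capture static and slowly varying clutter; the default removes
#' the first two singular values. The top right-singular subspace is obtained
#' from the frames x frames Gram matrix, which is exact and avoids a full
#' decomposition of the tall Casorati matrix.
#'
#' @param stack A [frame_stack()].
#' @param n_remove Number of leading singular components to zero
#'   (0 <= n_remove < min(pixels, frames)).
#' @return A filtered [frame_stack()] (values may be negative).
#' @export
svd_clutter_filter <- function(stack, n_remove = 2L) {
  d <- dim(stack)
  npix <- d[1] * d[2]
  if (n_remove < 0 || n_remove >= min(npix, d[3])) {
    stop("svd_clutter_filter: n_remove must be in [0, min(pixels, frames))",
         call. = FALSE)
  }
  if (n_remove == 0) return(stack)
  cas <- matrix(stack, npix, d[3])
  eig <- eigen(crossprod(cas), symmetric = TRUE)
  v <- eig$vectors[, seq_len(n_remove), drop = FALSE]
  filt <- cas - (cas %*% v) %*% t(v)
  stack_like(stack, array(filt, dim = d))
}

#' Zero-phase temporal high-pass filter
#'
#' Applies a second-order Butterworth high-pass along the frame axis of every
#' pixel, forward and backward (zero phase), so moving-bubble positions are
#' not delayed and velocities are unbiased. The cutoff is a fraction of the
#' Nyquist frequency (frame_rate / 2); the default 0.01 keeps bubble
#' transients at mm/s channel speeds in the passband while rejecting DC and
#' slow clutter.
#'
#' @param stack A [frame_stack()].
#' @param order Filter order (default 2).
#' @param cutoff High-pass cutoff as a fraction of Nyquist, in (0, 1).
#' @return A filtered [frame_stack()].
#' @export
temporal_highpass <- function(stack, order = 2L, cutoff = 0.01) {
  if (cutoff <= 0 || cutoff >= 1) {
    stop("temporal_highpass: cutoff must be in (0, 1)", call. = FALSE)
  }
  d <- dim(stack)
  if (d[3] <= 3 * order) {
    stop("temporal_highpass: need more than 3 x order frames", call. = FALSE)
  }
  flt <- signal::butter(order, cutoff, type = "high")
  m <- t(matrix(stack, d[1] * d[2], d[3]))        # frames x pixels
  out <- filtfilt_mat(flt$b, flt$a, m)
  stack_like(stack, array(t(out), dim = d))
}

# Steady-state initial state (per unit input) for direct-form II transposed
# filtering, so step inputs produce no start-up transient.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  b <- b / a[1]; a <- a / a[1]
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# IIR filter applied down the rows of X (time x pixels), direct-form II
# transposed, state initialised to zi x first row.
lfilter_mat <- function(b, a, x, zi) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  p <- ncol(x)
  z <- zi %o% x[1, ]                   # (n-1) x p state
  y <- matrix(0, nrow(x), p)
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1, ]
    for (s in seq_len(n - 2)) {
      z[s, ] <- b[s + 1] * xt + z[s + 1, ] - a[s + 1] * yt
    }
    z[n - 1, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# Zero-phase (forward-backward) filtering of every column of X, with
# odd-reflection padding of 3 x (order) samples at both ends.
filtfilt_mat <- function(b, a, x) {
  n <- max(length(a), length(b))
  p <- 3 * (n - 1)
  nt <- nrow(x)
  top <- 2 * x[rep(1, p), , drop = FALSE] - x[(p + 1):2, , drop = FALSE]
  bot <- 2 * x[rep(nt, p), , drop = FALSE] -
    x[(nt - 1):(nt - p), , drop = FALSE]
  xp <- rbind(top, x, bot)
  zi <- lfilter_zi(b, a)
  y <- lfilter_mat(b, a, xp, zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y <- lfilter_mat(b, a, y, zi)
  y <- y[nrow(y):1, , drop = FALSE]
  y[(p + 1):(p + nt), , drop = FALSE]
}

#' Adaptive peak detection
#'
#' Finds local maxima of the frame magnitude above an adaptive robust
#' threshold, median + k x MAD, both computed on the frame *as given* — pass
#' the signed filtered frame, whose MAD is a robust estimate of the noise
#' sd, rather than its magnitude, whose MAD underestimates it. A minimum
#' separation is enforced: among maxima closer than `min_separation` pixels
#' (Euclidean), only the brightest is kept (ties broken by smaller
#' (row, col)). Deterministic given the frame. Localized PSFs closer than
#' about four pixels cannot be told apart, hence the default separation of 4
#' on the upsampled grid.
#'
#' @param frame A numeric matrix (signed filter output or a non-negative
#'   envelope; maxima are searched on `abs(frame)`).
#' @param min_separation Minimum peak separation in pixels (>= 1).
#' @param k Threshold multiplier: threshold = median + k x MAD.
#' @param threshold Optional fixed threshold overriding the adaptive rule.
#' @return A tibble with `row`, `col`, `value`, ordered by decreasing value.
#' @export
detect_peaks <- function(frame, min_separation = 4, k = 4, threshold = NULL) {
  stopifnot(min_separation >= 1)
  if (is.null(threshold)) {
    threshold <- stats::median(frame) + k * stats::mad(frame)
  }
  frame <- abs(frame)
  nr <- nrow(frame); nc <- ncol(frame)
  # only pixels above threshold can be peaks; check their 8 neighbours
  idx <- which(frame > threshold)
  if (length(idx) > 0) {
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    ok <- rep(TRUE, length(idx))
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rn <- r + dr; cn <- c + dc
      inb <- rn >= 1 & rn <= nr & cn >= 1 & cn <= nc
      nbv <- rep(-Inf, length(idx))
      nbv[inb] <- frame[cbind(rn[inb], cn[inb])]
      ok <- ok & frame[idx] >= nbv
    }
    idx <- idx[ok]
  }
  if (length(idx) == 0) {
    return(tibble::tibble(row = integer(), col = integer(), value = double()))
  }
  cand <- tibble::tibble(
    row = (idx - 1) %% nr + 1,
    col = (idx - 1) %/% nr + 1,
    value = frame[idx]
  )
  cand <- cand[order(-cand$value, cand$row, cand$col), ]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    sel <- which(keep)
    if (length(sel) == 0 ||
        all((cand$row[sel] - cand$row[i])^2 + (cand$col[sel] - cand$col[i])^2
            >= min_separation^2)) {
      keep[i] <- TRUE
    }
  }
  cand[keep, ]
}

#' Subpixel localization by weighted centroid
#'
#' Computes the intensity-weighted centroid of an odd-sized window around
#' each detected peak, after subtracting the window minimum (local background
#' removal). Windows are clipped at the image border.
#'
#' @param frame A numeric matrix.
#' @param peaks A tibble with integer `row`, `col` (from [detect_peaks()]).
#' @param window Odd window width, >= 3.
#' @return A tibble with subpixel `row`, `col` and `intensity` (the peak
#'   pixel value).
#' @export
localize <- function(frame, peaks, window = 5) {
  if (window < 3 || window %% 2 != 1) {
    stop("localize: window must be odd and >= 3", call. = FALSE)
  }
  h <- (window - 1) / 2
  n <- nrow(peaks)
  row_out <- col_out <- inten <- numeric(n)
  for (i in seq_len(n)) {
    r0 <- max(1, peaks$row[i] - h); r1 <- min(nrow(frame), peaks$row[i] + h)
    c0 <- max(1, peaks$col[i] - h); c1 <- min(ncol(frame), peaks$col[i] + h)
    w <- frame[r0:r1, c0:c1, drop = FALSE]
    w <- w - min(w)
    tot <- sum(w)
    if (tot <= 0) {
      row_out[i] <- peaks$row[i]; col_out[i] <- peaks$col[i]
    } else {
      row_out[i] <- sum(rowSums(w) * (r0:r1)) / tot
      col_out[i] <- sum(colSums(w) * (c0:c1)) / tot
    }
    inten[i] <- frame[peaks$row[i], peaks$col[i]]
  }
  tibble::tibble(row = row_out, col = col_out, intensity = inten)
}

#' Run the full per-frame ULM localization chain
#'
#' upsample (bicubic, 2x) -> SVD clutter filter -> zero-phase temporal
#' high-pass -> magnitude -> adaptive peak detection -> weighted-centroid
#' subpixel localization, frame by frame. Identical input stacks yield
#' identical localization tables.
#'
#' @param stack A [frame_stack()].
#' @param upsample_factor Integer upsampling factor (default 2).
#' @param n_remove Singular components removed by the clutter filter.
#' @param hp_order,hp_cutoff Temporal high-pass parameters
#'   (see [temporal_highpass()]); `hp_cutoff = NULL` skips the filter.
#' @param min_separation,k Peak detection parameters (upsampled grid).
#' @param window Centroid window (upsampled grid).
#' @param block_size Process the stack in consecutive blocks of this many
#'   frames (the SVD filter and high-pass act per block, mirroring
#'   block-wise continuous acquisition); `NULL` processes the whole stack as
#'   one block.
#' @return A tibble of localizations: `frame`, `row`, `col` (subpixel, on the
#'   upsampled grid), `x_mm`, `z_mm`, `intensity`; attributes `pixel_size_mm`
#'   (upsampled pitch), `origin`, `frame_rate`, `upsample_factor`.
#' @export
ulm_localize <- function(stack, upsample_factor = 2L, n_remove = 2L,
                         hp_order = 2L, hp_cutoff = 0.01,
                         min_separation = 4, k = 4, window = 5,
                         block_size = NULL) {
  nf <- n_frames(stack)
  if (!is.null(block_size) && block_size < nf) {
    starts <- seq(1, nf, by = block_size)
    parts <- lapply(starts, function(s) {
      e <- min(s + block_size - 1, nf)
      sub <- stack_like(stack, stack[, , s:e, drop = FALSE])
      part <- ulm_localize(sub, upsample_factor, n_remove, hp_order,
                           hp_cutoff, min_separation, k, window,
                           block_size = NULL)
      part$frame <- part$frame + s - 1L
      part
    })
    res <- dplyr::bind_rows(lapply(parts, tibble::as_tibble))
    return(restore_loc_attrs(res, attributes(parts[[1]])))
  }
  up <- upsample_stack(stack, upsample_factor)
  filt <- svd_clutter_filter(up, n_remove)
  if (!is.null(hp_cutoff)) filt <- temporal_highpass(filt, hp_order, hp_cutoff)
  pitch <- attr(up, "pixel_size_mm")
  origin <- attr(up, "origin")
  out <- vector("list", n_frames(filt))
  for (f in seq_len(n_frames(filt))) {
    # threshold statistics come from the signed frame; maxima and centroids
    # are taken on the magnitude
    pk <- detect_peaks(filt[, , f], min_separation, k)
    if (nrow(pk) == 0) next
    loc <- localize(abs(filt[, , f]), pk, window)
    out[[f]] <- dplyr::bind_cols(tibble::tibble(frame = f), loc)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(frame = integer(), row = double(), col = double(),
                          intensity = double())
  }
  res$x_mm <- origin[1] + (res$col - 1) * pitch
  res$z_mm <- origin[2] + (res$row - 1) * pitch
  res <- res[, c("frame", "row", "col", "x_mm", "z_mm", "intensity")]
  structure(res, pixel_size_mm = pitch, origin = origin,
            frame_rate = attr(stack, "frame_rate"),
            upsample_factor = upsample_factor)
}

#' Write a localization table as CSV
#'
#' @param localizations Tibble from [ulm_localize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(localizations, path) {
  readr::write_csv(
    dplyr::select(localizations, "frame", "row", "col", "x_mm", "z_mm",
                  "intensity"), path)
  invisible(path)
}
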