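# Shared fixture builders; everything is generated in code at test time.

no_scatterers <- function() {
  tibble::tibble(row = numeric(), col = numeric(), amp = numeric())
}

# A single straight channel along +x (one inlet, one outlet).
single_channel <- function(width_um = 300, length_mm = 1.4,
                           flow_ml_min = 0.02) {
  net <- channel_network(tibble::tibble(
    id = "chan", x0 = 0, z0 = 0, x1 = length_mm, z1 = 0,
    width_um = width_um, height_um = 300
  ))
  flow_split(net, flow_config(flow_ml_min))
}

# Sampled isotropic Gaussian on an n x n grid centred at (r0, c0).
gaussian_frame <- function(n, r0, c0, sigma = 1.5, amp = 1) {
  amp * outer(seq_len(n), seq_len(n), function(i, j) {
    exp(-((i - r0)^2 + (j - c0)^2) / (2 * sigma^2))
  })
}

# Independent naive bicubic oracle: per-output-pixel Catmull-Rom kernel sum
# with clamped (edge-replicated) taps; same convention as the implementation
# but written as a direct nested loop.
naive_bicubic <- function(m, factor) {
  kern <- function(x, a = -0.5) {
    x <- abs(x)
    if (x <= 1) (a + 2) * x^3 - (a + 3) * x^2 + 1
    else if (x < 2) a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a
    else 0
  }
  interp1 <- function(v, p) {
    base <- floor(p)
    acc <- 0
    for (t in (base - 1):(base + 2)) {
      acc <- acc + kern(p - t) * v[min(max(t, 1), length(v))]
    }
    acc
  }
  nr <- nrow(m) * factor; nc <- ncol(m) * factor
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    pi <- (i - 0.5) / factor + 0.5
    rowvals <- vapply(seq_len(ncol(m)), function(j) interp1(m[, j], pi),
                      numeric(1))
    for (j in seq_len(nc)) {
      out[i, j] <- interp1(rowvals, (j - 0.5) / factor + 0.5)
    }
  }
  out
}

# Localization table for synthetic track tests.
make_locs <- function(frame, row, col, pitch = 0.0125, origin = c(0, 0)) {
  structure(tibble::tibble(
    frame = frame, row = row, col = col,
    x_mm = origin[1] + (col - 1) * pitch,
    z_mm = origin[2] + (row - 1) * pitch,
    intensity = 1
  ), pixel_size_mm = pitch, origin = origin, frame_rate = 250,
     upsample_factor = 2L)
}
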