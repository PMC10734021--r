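#' Acquisition configuration for the simulator
#'
#' Describes the emulated ultrafast contrast acquisition: grid, frame rate,
#' point-spread function, imaging mode and noise. Defaults follow the
#' acquisition the simulator emulates: continuous 1500-frame blocks at
#' 250 Hz, contrast-pulse-sequence (CPS) imaging with transmit weights
#' (0.5, -1, 0.5), and a Gaussian PSF.
#'
#' @param frame_rate Frames per second, Hz.
#' @param block_size Frames per acquisition block.
#' @param n_frames Total frames to simulate.
#' @param rows,cols Grid size in pixels.
#' @param pixel_size_mm Pixel pitch, mm.
#' @param psf_sigma_px Isotropic Gaussian PSF sigma on the original grid, px.
#' @param mode `"CPS"` (linear echoes cancel exactly) or `"BMODE"` (linear
#'   scatterers and bubbles both contribute).
#' @param noise_sd Additive Gaussian noise sd, in units of the unit bubble
#'   amplitude; frames are clipped at zero.
#' @param scatterer_density Fraction of off-channel pixels carrying a static
#'   linear scatterer (emulates tissue-mimicking powder in the phantom body).
#' @param concentration Microbubble concentration, MB/mL.
#' @param detect_fraction Fraction of injected microbubbles that yield a
#'   localizable nonlinear echo and are therefore simulated and rendered
#'   (Poisson thinning of the arrival process). Only a sparse subpopulation
#'   of a clinical-concentration bolus produces isolated, trackable echoes.
#' @param cps_gain Relative amplitude of the nonlinear bubble residual in CPS
#'   mode.
#' @param radiation_drift `NULL`, or `list(drift_mm_s =, stick_prob =)`
#'   enabling a constant acoustic-radiation-force drift in +z with a per-frame
#'   sticking probability once a bubble reaches the far (+z) wall. Magnitudes
#'   are illustrative; the effect is not calibrated.
#' @param rng_seed Integer seed; every stochastic draw in a sequence comes
#'   from one generator seeded with it.
#' @return A list of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 250, block_size = 1500,
                               n_frames = 1500, rows = 128, cols = 128,
                               pixel_size_mm = 0.025, psf_sigma_px = 1.5,
                               mode = c("CPS", "BMODE"), noise_sd = 0.01,
                               scatterer_density = 0, concentration = 6.4e6,
                               detect_fraction = 0.02, cps_gain = 1,
                               radiation_drift = NULL, rng_seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(frame_rate > 0, pixel_size_mm > 0, psf_sigma_px > 0,
            noise_sd >= 0, n_frames >= 1, rows >= 8, cols >= 8,
            scatterer_density >= 0, scatterer_density <= 1,
            concentration >= 0, detect_fraction >= 0, detect_fraction <= 1)
  structure(list(frame_rate = frame_rate, block_size = block_size,
                 n_frames = n_frames, rows = rows, cols = cols,
                 pixel_size_mm = pixel_size_mm, psf_sigma_px = psf_sigma_px,
                 mode = mode, noise_sd = noise_sd,
                 scatterer_density = scatterer_density,
                 concentration = concentration,
                 detect_fraction = detect_fraction, cps_gain = cps_gain,
                 radiation_drift = radiation_drift,
                 rng_seed = as.integer(rng_seed)),
            class = "acquisition_config")
}

#' Poisson microbubble arrivals at the inlet
#'
#' Arrivals form a Poisson process with rate lambda = concentration x flow
#' rate (per second). Each arrival enters at the inlet with a lateral offset
#' drawn from the flux-weighted entry distribution: the probability of
#' entering on a streamline is proportional to the local profile velocity,
#' p(u) proportional to (1 - u^2), so faster streamlines carry
#' proportionally more bubbles.
#'
#' Draws from R's global random generator; seed upstream for reproducibility.
#'
#' @param concentration MB/mL (>= 0).
#' @param flow_ml_min Inlet flow rate, mL/min (>= 0).
#' @param dt Time interval, s (>= 0).
#' @return A tibble with one row per arrival: `lateral_offset` in [-1, 1] and
#'   `frac_dt` in [0, 1), the fraction of `dt` already elapsed at arrival.
#' @examples
#' set.seed(1)
#' nrow(seed_bubbles(6.4e6, 0.02, 1))  # ~2133 arrivals per second
#' @export
seed_bubbles <- function(concentration, flow_ml_min, dt) {
  stopifnot(concentration >= 0, flow_ml_min >= 0, dt >= 0)
  lambda <- concentration * flow_ml_min / 60 * dt
  n <- stats::rpois(1, lambda)
  tibble::tibble(
    lateral_offset = sample_flux_offset(n),
    frac_dt = stats::runif(n)
  )
}

# Rejection sampling from p(u) proportional to (1 - u^2) on [-1, 1].
sample_flux_offset <- function(n) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16, 2 * (n - length(out)))
    u <- stats::runif(m, -1, 1)
    out <- c(out, u[stats::runif(m) < (1 - u^2)])
  }
  out[seq_len(n)]
}

# Per-segment kinematic tables used by the advection step.
segment_kinematics <- function(network) {
  sv <- segment_velocities(network)
  len <- sv$length_mm
  ax <- (sv$x1 - sv$x0) / len
  az <- (sv$z1 - sv$z0) / len
  end_keys <- node_key(sv$x1, sv$z1)
  daughters <- lapply(end_keys, function(k) {
    ids <- network$nodes[[k]]$outof
    match(ids, sv$id)
  })
  q <- sv$flow_ml_min
  probs <- lapply(daughters, function(d) {
    if (length(d) == 0) return(numeric(0))
    p <- q[d]
    if (sum(p) <= 0) rep(1 / length(d), length(d)) else p / sum(p)
  })
  list(id = sv$id, x0 = sv$x0, z0 = sv$z0, ax = ax, az = az, len = len,
       half_w = sv$width_um / 2000, v = sv$mean_v_mm_s,
       daughters = daughters, probs = probs)
}

new_bubble_state <- function() {
  tibble::tibble(id = integer(), seg = integer(), s_mm = double(),
                 u = double(), stuck = logical(), birth_frame = integer())
}

#' Advect bubbles through the network for one time step
#'
#' Each live bubble moves along its segment axis by its local streamline
#' speed, 1.5 V_mean (1 - u^2), times `dt`. At a junction it enters a
#' daughter channel with probability proportional to the daughter flow,
#' keeping its lateral offset. Bubbles leaving an outlet are removed. With
#' `radiation_drift` enabled, bubbles also drift towards +z and may stick
#' permanently at the far wall (`stuck` flag); stuck bubbles stop moving but
#' remain visible.
#'
#' @param bubbles Bubble state tibble (columns `id`, `seg`, `s_mm`, `u`,
#'   `stuck`, `birth_frame`).
#' @param network A flow-assigned [channel_network()], or the precomputed
#'   kinematics from it.
#' @param dt Time step, s.
#' @param radiation_drift See [acquisition_config()].
#' @return The updated bubble state tibble.
#' @export
advect_bubbles <- function(bubbles, network, dt, radiation_drift = NULL) {
  kin <- if (inherits(network, "channel_network")) {
    segment_kinematics(network)
  } else network
  if (nrow(bubbles) == 0 || dt == 0) return(bubbles)

  live <- !bubbles$stuck
  if (!is.null(radiation_drift) && any(live)) {
    hw <- kin$half_w[bubbles$seg[live]]
    du <- radiation_drift$drift_mm_s * kin$ax[bubbles$seg[live]] * dt / hw
    u_new <- bubbles$u[live] + du
    at_wall <- abs(u_new) >= 1
    if (any(at_wall)) {
      stick <- at_wall & stats::runif(length(u_new)) < radiation_drift$stick_prob
      u_new[at_wall] <- sign(u_new[at_wall]) * 0.999
      u_new[stick] <- sign(u_new[stick])
      bubbles$stuck[live][stick] <- TRUE
    }
    bubbles$u[live] <- u_new
    live <- !bubbles$stuck
  }

  sp <- 1.5 * kin$v[bubbles$seg] * (1 - bubbles$u^2)
  t_left <- ifelse(live, dt, 0)
  s <- bubbles$s_mm
  # Advance, hopping junctions until the step's time budget is used up.
  repeat {
    moving <- which(t_left > 0 & sp > 0)
    if (length(moving) == 0) break
    s_try <- s[moving] + sp[moving] * t_left[moving]
    over <- s_try > kin$len[bubbles$seg[moving]]
    s[moving[!over]] <- s_try[!over]
    t_left[moving[!over]] <- 0
    for (j in moving[over]) {
      seg <- bubbles$seg[j]
      t_left[j] <- t_left[j] - (kin$len[seg] - s[j]) / sp[j]
      d <- kin$daughters[[seg]]
      if (length(d) == 0) {        # outlet: mark exited
        bubbles$seg[j] <- NA_integer_
        t_left[j] <- 0
      } else {
        pick <- if (length(d) == 1) d else {
          d[sample.int(length(d), 1, prob = kin$probs[[seg]])]
        }
        bubbles$seg[j] <- pick
        s[j] <- 0
        sp[j] <- 1.5 * kin$v[pick] * (1 - bubbles$u[j]^2)
        if (sp[j] <= 0) t_left[j] <- 0
      }
    }
  }
  bubbles$s_mm <- s
  bubbles[!is.na(bubbles$seg), , drop = FALSE]
}

bubble_positions <- function(bubbles, kin) {
  i <- bubbles$seg
  nx <- -kin$az[i]; nz <- kin$ax[i]
  tibble::tibble(
    id = bubbles$id,
    x_mm = kin$x0[i] + bubbles$s_mm * kin$ax[i] + bubbles$u * kin$half_w[i] * nx,
    z_mm = kin$z0[i] + bubbles$s_mm * kin$az[i] + bubbles$u * kin$half_w[i] * nz,
    segment = kin$id[i],
    u = bubbles$u,
    speed_mm_s = ifelse(bubbles$stuck, 0, 1.5 * kin$v[i] * (1 - bubbles$u^2)),
    stuck = bubbles$stuck
  )
}

#' Static linear scatterer field
#'
#' Places point scatterers with random amplitudes at random off-channel
#' pixels; the field is fixed across all frames (static tissue-mimicking
#' background). Draws from R's global random generator.
#'
#' @param density Per-pixel placement probability, in [0, 1].
#' @param rows,cols Grid size.
#' @param channel_mask Optional logical matrix; pixels where TRUE are excluded.
#' @return A tibble with `row`, `col`, `amp`.
#' @export
make_scatterer_field <- function(density, rows, cols, channel_mask = NULL) {
  stopifnot(density >= 0, density <= 1)
  ok <- matrix(TRUE, rows, cols)
  if (!is.null(channel_mask)) ok <- !channel_mask
  idx <- which(ok & matrix(stats::runif(rows * cols) < density, rows, cols))
  tibble::tibble(
    row = (idx - 1) %% rows + 1,
    col = (idx - 1) %/% rows + 1,
    amp = stats::runif(length(idx), 0.2, 1)
  )
}

# Accumulate Gaussian PSFs at (possibly subpixel) positions into a matrix.
stamp_psf <- function(rows, cols, row, col, amp, sigma) {
  out <- matrix(0, rows, cols)
  n <- length(row)
  if (n == 0) return(out)
  r <- ceiling(4 * sigma)
  off <- seq(-r, r)
  k <- length(off)
  base_r <- round(row); base_c <- round(col)
  ri <- rep(base_r, each = k^2) + rep(off, times = k * n)
  ci <- rep(base_c, each = k^2) + rep(rep(off, each = k), times = n)
  rr <- rep(row, each = k^2); cc <- rep(col, each = k^2)
  aa <- rep(amp, each = k^2)
  val <- aa * exp(-((ri - rr)^2 + (ci - cc)^2) / (2 * sigma^2))
  keep <- ri >= 1 & ri <= rows & ci >= 1 & ci <= cols
  idx <- (ci[keep] - 1) * rows + ri[keep]
  agg <- rowsum(val[keep], idx)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Render one post-beamformed envelope frame
#'
#' Every source contributes a Gaussian PSF at its position. In B-mode,
#' bubbles and linear scatterers both contribute. In CPS mode the three-pulse
#' transmit weights (0.5, -1, 0.5) are summed explicitly over the linear
#' responses, which cancels them exactly (to the last bit: 0.5 s - s +
#' 0.5 s = 0); bubbles contribute their nonlinear residual with relative
#' amplitude `cps_gain`. Additive Gaussian noise is applied last and the
#' frame clipped at zero.
#'
#' @param bubbles A tibble with `row`, `col` (subpixel) and `amp`.
#' @param scatterers A tibble with `row`, `col`, `amp` (see
#'   [make_scatterer_field()]).
#' @param config An [acquisition_config()].
#' @return A `rows x cols` numeric matrix.
#' @export
render_frame <- function(bubbles, scatterers, config) {
  rows <- config$rows; cols <- config$cols
  f_bub <- stamp_psf(rows, cols, bubbles$row, bubbles$col, bubbles$amp,
                     config$psf_sigma_px)
  f_sca <- stamp_psf(rows, cols, scatterers$row, scatterers$col,
                     scatterers$amp, config$psf_sigma_px)
  if (config$mode == "CPS") {
    lin <- f_bub + f_sca
    cps_weights <- c(0.5, -1, 0.5)
    frame <- cps_weights[1] * lin + cps_weights[2] * lin +
      cps_weights[3] * lin                      # exact zero for linear echoes
    frame <- frame + config$cps_gain * f_bub    # nonlinear bubble residual
  } else {
    frame <- f_bub + f_sca
  }
  if (config$noise_sd > 0) {
    frame <- frame + matrix(stats::rnorm(rows * cols, sd = config$noise_sd),
                            rows, cols)
  }
  pmax(frame, 0)
}

mm_to_px <- function(x_mm, z_mm, origin, pitch) {
  list(row = (z_mm - origin[2]) / pitch + 1,
       col = (x_mm - origin[1]) / pitch + 1)
}

#' Simulate a full contrast acquisition
#'
#' Runs the seed / advect / render loop over `n_frames` frames: detectable
#' microbubbles arrive at the inlet as a thinned Poisson process with rate
#' concentration x flow rate x `detect_fraction`, ride the laminar profile
#' through the network, and are rendered with a Gaussian PSF in CPS or B-mode
#' with additive noise. Fully reproducible from `config$rng_seed`.
#'
#' @param network A [channel_network()] (flows are assigned from
#'   `flow` if missing).
#' @param flow A [flow_config()].
#' @param config An [acquisition_config()].
#' @return A list with elements:
#'   `stack` (a [frame_stack()]);
#'   `truth` (tibble of true positions: frame, id, x_mm, z_mm, segment, u,
#'   speed_mm_s, stuck — each id is one true track);
#'   `mask` (channel mask on the original grid);
#'   `network` (the flow-assigned network); and `origin`.
#' @export
generate_sequence <- function(network, flow = flow_config(),
                              config = acquisition_config()) {
  if (anyNA(network$segments$flow_ml_min)) {
    network <- flow_split(network, flow)
  }
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$rng_seed)

  kin <- segment_kinematics(network)
  inlet <- match(network_inlets(network), kin$id)
  origin <- centered_origin(network, config$rows, config$cols,
                            config$pixel_size_mm)
  mask <- channel_mask(network, config$rows, config$cols, origin,
                       config$pixel_size_mm)
  scatterers <- make_scatterer_field(config$scatterer_density, config$rows,
                                     config$cols, mask)
  dt <- 1 / config$frame_rate
  rate_flow <- network$segments$flow_ml_min[
    match(network_inlets(network), network$segments$id)]

  bubbles <- new_bubble_state()
  next_id <- 1L
  arr <- array(0, dim = c(config$rows, config$cols, config$n_frames))
  truth <- vector("list", config$n_frames)

  for (f in seq_len(config$n_frames)) {
    bubbles <- advect_bubbles(bubbles, kin, dt, config$radiation_drift)
    arrivals <- seed_bubbles(config$concentration * config$detect_fraction,
                             rate_flow, dt)
    if (nrow(arrivals) > 0) {
      sp0 <- 1.5 * kin$v[inlet] * (1 - arrivals$lateral_offset^2)
      newb <- tibble::tibble(
        id = next_id + seq_len(nrow(arrivals)) - 1L,
        seg = inlet,
        s_mm = sp0 * dt * (1 - arrivals$frac_dt),
        u = arrivals$lateral_offset,
        stuck = FALSE,
        birth_frame = f
      )
      next_id <- next_id + nrow(arrivals)
      # arrivals overshooting the inlet segment within their first partial
      # frame are advanced through advect on the next frame; clamp here
      newb$s_mm <- pmin(newb$s_mm, kin$len[inlet])
      bubbles <- dplyr::bind_rows(bubbles, newb)
    }
    pos <- bubble_positions(bubbles, kin)
    px <- mm_to_px(pos$x_mm, pos$z_mm, origin, config$pixel_size_mm)
    arr[, , f] <- render_frame(
      tibble::tibble(row = px$row, col = px$col, amp = 1),
      scatterers, config)
    truth[[f]] <- dplyr::bind_cols(tibble::tibble(frame = f), pos)
  }

  list(
    stack = frame_stack(arr, config$frame_rate, config$pixel_size_mm, origin),
    truth = dplyr::bind_rows(truth),
    mask = mask,
    network = network,
    origin = origin,
    scatterers = scatterers
  )
}

#' Write ground-truth positions as CSV
#'
#' @param truth The `truth` tibble from [generate_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_csv(
    dplyr::select(truth, "frame", track_id = "id", "x_mm", "z_mm"), path)
  invisible(path)
}
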