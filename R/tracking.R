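#' Link localizations into tracks across consecutive frames
#'
#' Greedy mutual-nearest-neighbour linking: candidate pairs between frame t
#' track ends and frame t+1 localizations are taken in ascending distance
#' order (ties broken lexicographically for determinism); each end and each
#' new localization is used at most once, and pairs farther than
#' `max_link_distance` are rejected. Unmatched localizations start new
#' tracks, so every localization belongs to exactly one track. A missed frame
#' always terminates a track (tracks are strictly consecutive in frame
#' index).
#'
#' @param localizations Tibble from [ulm_localize()] (needs `frame`, `row`,
#'   `col`; any further columns are carried along).
#' @param max_link_distance Link gate in (upsampled) pixels; `NULL` means
#'   ungated. See [link_gate()] for the displacement-based default used by
#'   the experiment runner.
#' @return The input tibble with a `track_id` column, ordered by track and
#'   frame.
#' @export
link_tracks <- function(localizations, max_link_distance = NULL) {
  gate <- if (is.null(max_link_distance)) Inf else max_link_distance
  loc <- dplyr::arrange(tibble::as_tibble(localizations),
                        .data$frame, .data$row, .data$col)
  n <- nrow(loc)
  track_id <- integer(n)
  if (n == 0) {
    loc$track_id <- track_id
    return(loc)
  }
  frames <- loc$frame
  next_track <- 1L
  prev_idx <- integer(0)        # row indices of active track ends
  prev_frame <- -Inf
  for (f in sort(unique(frames))) {
    cur_idx <- which(frames == f)
    if (f != prev_frame + 1 || length(prev_idx) == 0) {
      matched_cur <- rep(FALSE, length(cur_idx))
    } else {
      d2 <- outer(loc$row[prev_idx], loc$row[cur_idx], "-")^2 +
        outer(loc$col[prev_idx], loc$col[cur_idx], "-")^2
      ord <- order(d2)
      used_prev <- rep(FALSE, length(prev_idx))
      matched_cur <- rep(FALSE, length(cur_idx))
      for (o in ord) {
        if (d2[o] > gate^2) break
        i <- (o - 1) %% length(prev_idx) + 1
        j <- (o - 1) %/% length(prev_idx) + 1
        if (used_prev[i] || matched_cur[j]) next
        used_prev[i] <- TRUE
        matched_cur[j] <- TRUE
        track_id[cur_idx[j]] <- track_id[prev_idx[i]]
      }
    }
    for (j in which(!matched_cur)) {
      track_id[cur_idx[j]] <- next_track
      next_track <- next_track + 1L
    }
    prev_idx <- cur_idx
    prev_frame <- f
  }
  loc$track_id <- track_id
  att <- attributes(localizations)
  dplyr::arrange(restore_loc_attrs(loc, att), .data$track_id, .data$frame)
}

restore_loc_attrs <- function(x, att) {
  for (nm in c("pixel_size_mm", "origin", "frame_rate", "upsample_factor")) {
    attr(x, nm) <- att[[nm]]
  }
  x
}

#' Default link gate from the expected maximum displacement
#'
#' Twice the per-frame displacement of the fastest expected bubble,
#' 2 x v_max / frame_rate, converted to (upsampled) pixels.
#'
#' @param v_max_mm_s Maximum expected speed, mm/s (e.g. 1.5 x the largest
#'   channel mean velocity).
#' @param frame_rate Hz.
#' @param pixel_size_mm Pitch of the grid the localizations live on, mm.
#' @return Gate in pixels.
#' @export
link_gate <- function(v_max_mm_s, frame_rate, pixel_size_mm) {
  2 * v_max_mm_s / frame_rate / pixel_size_mm
}

#' Keep only tracks longer than a minimum number of frames
#'
#' Only bubbles tracked for more than `min_frames` consecutive frames are
#' kept (strict inequality: at the default 10, a track needs at least 11
#' localizations).
#'
#' @param tracks Tibble with a `track_id` column (from [link_tracks()]).
#' @param min_frames Strict lower bound on track length in frames.
#' @return The filtered tibble.
#' @export
filter_tracks <- function(tracks, min_frames = 10) {
  stopifnot(min_frames >= 1)
  att <- attributes(tracks)
  out <- dplyr::filter(dplyr::group_by(tracks, .data$track_id),
                       dplyr::n() > min_frames)
  restore_loc_attrs(dplyr::ungroup(out), att)
}

#' Per-step displacement speeds
#'
#' The speed of each track step is the Euclidean displacement between
#' consecutive frames (mm) times the frame rate.
#'
#' @param tracks Tibble with `track_id`, `frame`, `x_mm`, `z_mm`, plus `row`,
#'   `col` if map accumulation is intended.
#' @param frame_rate Hz; taken from the table's attributes if absent.
#' @return A tibble of steps: `track_id`, `frame` (of the step start),
#'   endpoint coordinates, and `speed_mm_s`.
#' @export
compute_velocities <- function(tracks, frame_rate = NULL) {
  if (is.null(frame_rate)) frame_rate <- attr(tracks, "frame_rate")
  stopifnot(!is.null(frame_rate))
  has_px <- all(c("row", "col") %in% names(tracks))
  steps <- dplyr::reframe(
    dplyr::group_by(dplyr::arrange(tracks, .data$track_id, .data$frame),
                    .data$track_id),
    frame = .data$frame[-dplyr::n()],
    x0 = .data$x_mm[-dplyr::n()], z0 = .data$z_mm[-dplyr::n()],
    x1 = .data$x_mm[-1], z1 = .data$z_mm[-1],
    row0 = if (has_px) .data$row[-dplyr::n()] else NA_real_,
    col0 = if (has_px) .data$col[-dplyr::n()] else NA_real_,
    row1 = if (has_px) .data$row[-1] else NA_real_,
    col1 = if (has_px) .data$col[-1] else NA_real_
  )
  steps$speed_mm_s <- sqrt((steps$x1 - steps$x0)^2 +
                           (steps$z1 - steps$z0)^2) * frame_rate
  steps
}

#' Per-track summary speeds
#'
#' @param steps Step table from [compute_velocities()].
#' @return One row per track: number of steps and mean step speed.
#' @export
track_summary <- function(steps) {
  dplyr::summarise(dplyr::group_by(steps, .data$track_id),
                   n_steps = dplyr::n(),
                   mean_speed_mm_s = mean(.data$speed_mm_s),
                   .groups = "drop")
}

# Integer pixel line between two cells (Bresenham).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  n <- max(dr, dc) + 1
  rows <- integer(n); cols <- integer(n)
  err <- dr - dc
  r <- r0; c <- c0
  for (i in seq_len(n)) {
    rows[i] <- r; cols[i] <- c
    if (r == r1 && c == c1) { rows <- rows[1:i]; cols <- cols[1:i]; break }
    e2 <- 2 * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr) { err <- err + dr; c <- c + sc }
  }
  list(row = rows, col = cols)
}

#' Accumulate super-resolved density and velocity maps
#'
#' Each localization increments its (rounded) cell in the density map. Each
#' step's speed is painted onto every cell its segment crosses (Bresenham
#' traversal), and a velocity cell is the mean of the speeds painted into it
#' (NA where no step passed).
#'
#' @param tracks Filtered track table (needs `row`, `col`).
#' @param dim Length-2 integer: map size (rows, cols) on the upsampled grid.
#' @param frame_rate Hz; from attributes if absent.
#' @return A list of class `ulm_maps`: `density` (integer matrix),
#'   `velocity` (matrix, mm/s, NA where undefined), plus the grid metadata
#'   carried from the track table when available.
#' @export
accumulate_maps <- function(tracks, dim, frame_rate = NULL) {
  density <- matrix(0L, dim[1], dim[2])
  velocity_sum <- matrix(0, dim[1], dim[2])
  velocity_n <- matrix(0L, dim[1], dim[2])
  if (nrow(tracks) > 0) {
    r <- pmin(pmax(round(tracks$row), 1), dim[1])
    c <- pmin(pmax(round(tracks$col), 1), dim[2])
    tab <- table(factor((c - 1) * dim[1] + r, levels = seq_len(prod(dim))))
    density <- matrix(as.integer(tab), dim[1], dim[2])
    steps <- compute_velocities(tracks, frame_rate)
    for (i in seq_len(nrow(steps))) {
      ln <- bresenham(
        pmin(pmax(round(steps$row0[i]), 1), dim[1]),
        pmin(pmax(round(steps$col0[i]), 1), dim[2]),
        pmin(pmax(round(steps$row1[i]), 1), dim[1]),
        pmin(pmax(round(steps$col1[i]), 1), dim[2]))
      idx <- (ln$col - 1) * dim[1] + ln$row
      velocity_sum[idx] <- velocity_sum[idx] + steps$speed_mm_s[i]
      velocity_n[idx] <- velocity_n[idx] + 1L
    }
  }
  velocity <- ifelse(velocity_n > 0, velocity_sum / velocity_n, NA_real_)
  structure(list(density = density, velocity = velocity,
                 pixel_size_mm = attr(tracks, "pixel_size_mm"),
                 origin = attr(tracks, "origin")),
            class = "ulm_maps")
}

#' @export
print.ulm_maps <- function(x, ...) {
  cat(sprintf("<ulm_maps> %d x %d px, %d localizations, %d velocity cells\n",
              nrow(x$density), ncol(x$density), sum(x$density),
              sum(!is.na(x$velocity))))
  invisible(x)
}

#' Lateral velocity profile across a channel
#'
#' Averages `n_sections` successive cross sections perpendicular to the
#' segment axis (one map pixel apart, centred on the segment), sampling the
#' velocity map at one-pixel lateral steps across the channel width.
#'
#' @param maps An `ulm_maps` object (needs grid metadata), or a velocity
#'   matrix if `origin`/`pixel_size_mm` are given.
#' @param segment One row of a network's segment table (or a list with `x0`,
#'   `z0`, `x1`, `z1`, `width_um`).
#' @param n_sections Number of successive cross sections to average.
#' @param origin,pixel_size_mm Grid metadata overriding the map's own.
#' @return A tibble: `offset_frac` (lateral position as a fraction of the
#'   half-width), `lateral_mm`, `speed_mm_s` (NA where never sampled), `n`.
#' @export
velocity_profile <- function(maps, segment, n_sections = 25,
                             origin = NULL, pixel_size_mm = NULL) {
  vmap <- if (inherits(maps, "ulm_maps")) maps$velocity else maps
  origin <- origin %||% maps$origin
  pixel_size_mm <- pixel_size_mm %||% maps$pixel_size_mm
  stopifnot(!is.null(origin), !is.null(pixel_size_mm))
  len <- sqrt((segment$x1 - segment$x0)^2 + (segment$z1 - segment$z0)^2)
  ax <- (segment$x1 - segment$x0) / len
  az <- (segment$z1 - segment$z0) / len
  nx <- -az; nz <- ax
  half_w <- segment$width_um / 2000
  s_mid <- len / 2
  s_pos <- s_mid + (seq_len(n_sections) - (n_sections + 1) / 2) * pixel_size_mm
  s_pos <- pmin(pmax(s_pos, 0), len)
  lat <- seq(-half_w, half_w, by = pixel_size_mm)
  sect <- expand.grid(s = s_pos, d = lat)
  x <- segment$x0 + sect$s * ax + sect$d * nx
  z <- segment$z0 + sect$s * az + sect$d * nz
  row <- round((z - origin[2]) / pixel_size_mm) + 1
  col <- round((x - origin[1]) / pixel_size_mm) + 1
  ok <- row >= 1 & row <= nrow(vmap) & col >= 1 & col <= ncol(vmap)
  if (!any(ok)) {
    stop("velocity_profile: segment lies outside the map", call. = FALSE)
  }
  v <- rep(NA_real_, nrow(sect))
  v[ok] <- vmap[cbind(row[ok], col[ok])]
  prof <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(d = sect$d, v = v), .data$d),
    speed_mm_s = if (all(is.na(.data$v))) NA_real_ else
      mean(.data$v, na.rm = TRUE),
    n = sum(!is.na(.data$v)), .groups = "drop")
  tibble::tibble(offset_frac = prof$d / half_w, lateral_mm = prof$d,
                 speed_mm_s = prof$speed_mm_s, n = prof$n)
}

#' Write a track table as CSV
#'
#' @param tracks Track table (localizations with `track_id`).
#' @param frame_rate Hz; from attributes if absent.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, frame_rate = NULL) {
  steps <- compute_velocities(tracks, frame_rate)
  speed_by <- stats::setNames(steps$speed_mm_s,
                              paste(steps$track_id, steps$frame))
  out <- dplyr::select(tracks, "track_id", "frame", "x_mm", "z_mm")
  out$speed_mm_s <- unname(speed_by[paste(out$track_id, out$frame)])
  readr::write_csv(out, path)
  invisible(path)
}

#' Write maps as CSV (long form) and TIFF
#'
#' @param maps An `ulm_maps` object.
#' @param prefix Path prefix; writes `<prefix>_density.csv/.tif` and
#'   `<prefix>_velocity.csv/.tif` (velocity NA stored as 0 in the TIFF).
#' @return The prefix, invisibly.
#' @export
write_maps <- function(maps, prefix) {
  for (what in c("density", "velocity")) {
    m <- maps[[what]]
    df <- tibble::tibble(
      row = rep(seq_len(nrow(m)), times = ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m)
    )
    readr::write_csv(df[!is.na(df$value) & df$value != 0, ],
                     paste0(prefix, "_", what, ".csv"))
    m[is.na(m)] <- 0
    tiff::writeTIFF(m / max(m, 1), paste0(prefix, "_", what, ".tif"),
                    bits.per.sample = 32L)
  }
  invisible(prefix)
}
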