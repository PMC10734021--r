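#' Planar rectangular-channel vessel networks
#'
#' A `channel_network` holds the ground-truth geometry of a flow phantom: a
#' set of straight rectangular channel segments in a single imaging plane,
#' connected at ideal zero-length junction nodes. Coordinates are continuous
#' planar millimetres with the origin at the inlet centre, `x` lateral and
#' `z` depth (increasing away from the transducer). Widths and heights are in
#' micrometres; flow rates in mL/min are assigned by [flow_split()].
#'
#' @param segments A data frame with one row per segment and columns
#'   `id` (character), `x0`, `z0`, `x1`, `z1` (mm), `width_um`, `height_um`,
#'   and optionally `flow_ml_min`.
#' @return An object of class `channel_network`: a list with elements
#'   `segments` (a tibble) and `nodes` (the junction connectivity map).
#' @examples
#' net <- build_bifurcation(300, 300, 45)
#' net
#' @export
channel_network <- function(segments) {
  segments <- tibble::as_tibble(segments)
  required <- c("id", "x0", "z0", "x1", "z1", "width_um", "height_um")
  missing_cols <- setdiff(required, names(segments))
  if (length(missing_cols) > 0) {
    stop("invalid geometry: segments lack column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"flow_ml_min" %in% names(segments)) segments$flow_ml_min <- NA_real_
  if (anyDuplicated(segments$id)) {
    stop("invalid geometry: duplicated segment ids", call. = FALSE)
  }
  if (any(segments$width_um <= 0) || any(segments$height_um <= 0)) {
    stop("invalid geometry: widths and heights must be positive", call. = FALSE)
  }
  len <- segment_lengths(segments)
  if (any(len <= 0)) {
    stop("invalid geometry: zero-length segment (start == end)", call. = FALSE)
  }
  net <- structure(list(segments = segments), class = "channel_network")
  net$nodes <- network_nodes(segments)
  inl <- network_inlets(net)
  out <- network_outlets(net)
  if (length(inl) != 1) {
    stop("invalid geometry: network must have exactly one inlet segment, found ",
         length(inl), call. = FALSE)
  }
  if (length(out) < 1) {
    stop("invalid geometry: network must have at least one outlet", call. = FALSE)
  }
  net
}

#' @export
print.channel_network <- function(x, ...) {
  cat("<channel_network> ", nrow(x$segments), " segments, inlet '",
      network_inlets(x), "', outlets: ",
      paste(network_outlets(x), collapse = ", "), "\n", sep = "")
  print(x$segments)
  invisible(x)
}

segment_lengths <- function(segments) {
  sqrt((segments$x1 - segments$x0)^2 + (segments$z1 - segments$z0)^2)
}

# Coincident endpoints (to 1e-6 mm) define junction nodes.
node_key <- function(x, z) paste(round(x, 6), round(z, 6), sep = "|")

network_nodes <- function(segments) {
  keys <- unique(c(node_key(segments$x0, segments$z0),
                   node_key(segments$x1, segments$z1)))
  lapply(stats::setNames(keys, keys), function(k) {
    list(
      into = segments$id[node_key(segments$x1, segments$z1) == k],
      outof = segments$id[node_key(segments$x0, segments$z0) == k]
    )
  })
}

#' @rdname channel_network
#' @param network A `channel_network`.
#' @export
network_inlets <- function(network) {
  hit <- vapply(network$nodes, function(n) {
    length(n$into) == 0 && length(n$outof) >= 1
  }, logical(1))
  unlist(lapply(network$nodes[hit], `[[`, "outof"), use.names = FALSE)
}

#' @rdname channel_network
#' @export
network_outlets <- function(network) {
  hit <- vapply(network$nodes, function(n) {
    length(n$outof) == 0 && length(n$into) >= 1
  }, logical(1))
  unlist(lapply(network$nodes[hit], `[[`, "into"), use.names = FALSE)
}

#' Build a bifurcating channel phantom
#'
#' Constructs the canonical two-outlet phantom: a main channel that continues
#' straight past the junction and a branching channel that splits off at a
#' given angle. Channel height defaults to 300 um, as used for the physical
#' phantoms the simulator emulates.
#'
#' @param main_width_um Main channel width in micrometres, in (0, 1000].
#' @param branch_width_um Branch width in micrometres, in (0, 1000].
#' @param angle_deg Bifurcation angle in degrees, strictly between 0 and 90.
#' @param lengths_mm Two lengths in mm: main channel before the junction, and
#'   each daughter channel after it.
#' @param height_um Channel height (the unimaged dimension), micrometres.
#' @return A [channel_network()] with segments `main_in`, `main_out`, `branch`.
#' @examples
#' build_bifurcation(300, 100, 45)
#' @export
build_bifurcation <- function(main_width_um, branch_width_um = main_width_um,
                              angle_deg, lengths_mm = c(1.5, 1.5),
                              height_um = 300) {
  check_width(main_width_um, "main_width_um")
  check_width(branch_width_um, "branch_width_um")
  if (!is.finite(angle_deg) || angle_deg <= 0 || angle_deg >= 90) {
    stop("invalid geometry: angle_deg must be strictly between 0 and 90",
         call. = FALSE)
  }
  if (length(lengths_mm) == 1) lengths_mm <- rep(lengths_mm, 2)
  if (any(!is.finite(lengths_mm)) || any(lengths_mm <= 0)) {
    stop("invalid geometry: lengths_mm must be positive", call. = FALSE)
  }
  a <- angle_deg * pi / 180
  l1 <- lengths_mm[1]; l2 <- lengths_mm[2]
  segs <- tibble::tibble(
    id = c("main_in", "main_out", "branch"),
    x0 = c(0, l1, l1),
    z0 = c(0, 0, 0),
    x1 = c(l1, l1 + l2, l1 + l2 * cos(a)),
    z1 = c(0, 0, l2 * sin(a)),
    width_um = c(main_width_um, main_width_um, branch_width_um),
    height_um = height_um
  )
  channel_network(segs)
}

#' Build a trifurcating channel phantom
#'
#' One channel splits into three equal-width channels at +/- `angle_deg` and
#' straight ahead. With `converging = TRUE` the three channels merge back into
#' a single outlet, as in classical microfluidic chips; otherwise each runs to
#' its own outlet.
#'
#' @param width_um Channel width (all channels), micrometres.
#' @param angle_deg Splitting angle of the two side channels, degrees.
#' @param converging Merge the three branches back into one outlet?
#' @param lengths_mm Lengths in mm: inlet, each branch, and (converging only)
#'   the final outlet.
#' @param height_um Channel height, micrometres.
#' @return A [channel_network()].
#' @examples
#' build_trifurcation(300, 30, converging = TRUE)
#' @export
build_trifurcation <- function(width_um = 300, angle_deg = 30,
                               converging = FALSE,
                               lengths_mm = c(1, 1, 0.8),
                               height_um = 300) {
  check_width(width_um, "width_um")
  if (!is.finite(angle_deg) || angle_deg <= 0 || angle_deg >= 90) {
    stop("invalid geometry: angle_deg must be strictly between 0 and 90",
         call. = FALSE)
  }
  a <- angle_deg * pi / 180
  l1 <- lengths_mm[1]; l2 <- lengths_mm[2]
  l3 <- if (length(lengths_mm) >= 3) lengths_mm[3] else l2
  dx <- l2 * cos(a); dz <- l2 * sin(a)
  if (!converging) {
    segs <- tibble::tibble(
      id = c("inlet", "branch_up", "branch_mid", "branch_down"),
      x0 = c(0, l1, l1, l1),
      z0 = c(0, 0, 0, 0),
      x1 = c(l1, l1 + dx, l1 + l2, l1 + dx),
      z1 = c(0, -dz, 0, dz),
      width_um = width_um, height_um = height_um
    )
  } else {
    # Side branches go out at +/- angle and come back; the middle branch runs
    # straight between the two junctions.
    xj2 <- l1 + 2 * dx
    segs <- tibble::tibble(
      id = c("inlet", "up_a", "up_b", "mid", "down_a", "down_b", "outlet"),
      x0 = c(0, l1, l1 + dx, l1, l1, l1 + dx, xj2),
      z0 = c(0, 0, -dz, 0, 0, dz, 0),
      x1 = c(l1, l1 + dx, xj2, xj2, l1 + dx, xj2, xj2 + l3),
      z1 = c(0, -dz, 0, 0, dz, 0, 0),
      width_um = width_um, height_um = height_um
    )
  }
  channel_network(segs)
}

check_width <- function(w, name) {
  if (!is.finite(w) || w <= 0 || w > 1000) {
    stop("invalid geometry: ", name, " must be in (0, 1000] um", call. = FALSE)
  }
  invisible(w)
}

#' Rectangular cross-section area
#'
#' @param width_um,height_um Channel width and height, micrometres.
#' @return Area in square metres.
#' @examples
#' cross_section_area(300, 300)  # 9e-08 m^2
#' @export
cross_section_area <- function(width_um, height_um) {
  if (any(!is.finite(width_um)) || any(width_um <= 0) ||
      any(!is.finite(height_um)) || any(height_um <= 0)) {
    stop("cross_section_area: width and height must be positive", call. = FALSE)
  }
  (width_um * 1e-6) * (height_um * 1e-6)
}

#' Mean channel velocity from conservation of mass
#'
#' The mean velocity in a channel is the volumetric flow rate divided by the
#' cross-section area, V = Q / A (conservation of mass for an incompressible
#' fluid). 1 mL/min is 1/60 x 1e-6 m^3/s.
#'
#' @param flow_ml_min Volumetric flow rate, mL/min (>= 0).
#' @param area_m2 Cross-section area, m^2 (> 0).
#' @return Mean velocity in mm/s.
#' @examples
#' expected_velocity(0.02, cross_section_area(300, 300))  # ~3.70 mm/s
#' @export
expected_velocity <- function(flow_ml_min, area_m2) {
  if (any(!is.finite(area_m2)) || any(area_m2 <= 0)) {
    stop("expected_velocity: area_m2 must be positive", call. = FALSE)
  }
  if (any(!is.finite(flow_ml_min)) || any(flow_ml_min < 0)) {
    stop("expected_velocity: flow_ml_min must be >= 0", call. = FALSE)
  }
  q_m3_s <- flow_ml_min * 1e-6 / 60
  (q_m3_s / area_m2) * 1000
}

#' Flow configuration for a phantom run
#'
#' @param inlet_flow_rate Inlet volumetric flow rate, mL/min (>= 0).
#' @param split_rule How flow divides among daughter channels at a junction:
#'   `"symmetric"` assigns equal mean velocity to all daughters (flow
#'   proportional to area; equal-area daughters get equal flow), `"resistance"`
#'   assigns flow inversely proportional to the hydraulic resistance of each
#'   daughter, R proportional to L / (w^3 h) (rectangular-slit approximation).
#'   Under the resistance rule, equal-area daughters still split evenly.
#' @return A list of class `flow_config`.
#' @export
flow_config <- function(inlet_flow_rate = 0.02,
                        split_rule = c("symmetric", "resistance")) {
  split_rule <- match.arg(split_rule)
  if (!is.finite(inlet_flow_rate) || inlet_flow_rate < 0) {
    stop("flow_config: inlet_flow_rate must be >= 0", call. = FALSE)
  }
  structure(list(inlet_flow_rate = inlet_flow_rate, split_rule = split_rule),
            class = "flow_config")
}

#' Assign flow rates throughout a network
#'
#' Propagates the inlet flow through every junction so that flow is conserved
#' exactly (sum in = sum out at every node), splitting among daughters by the
#' rule in `config` (see [flow_config()]).
#'
#' @param network A [channel_network()].
#' @param config A [flow_config()], or a single inlet flow rate in mL/min
#'   (symmetric split).
#' @return The network with `flow_ml_min` filled in for every segment.
#' @examples
#' net <- flow_split(build_bifurcation(300, 300, 45), flow_config(0.02))
#' segment_velocities(net)
#' @export
flow_split <- function(network, config = flow_config()) {
  if (is.numeric(config)) config <- flow_config(config)
  stopifnot(inherits(network, "channel_network"),
            inherits(config, "flow_config"))
  segs <- network$segments
  flows <- stats::setNames(rep(NA_real_, nrow(segs)), segs$id)
  flows[network_inlets(network)] <- config$inlet_flow_rate
  len <- stats::setNames(segment_lengths(segs), segs$id)
  area <- stats::setNames(cross_section_area(segs$width_um, segs$height_um),
                          segs$id)

  # Propagate node by node; a node is ready when all its inflows are assigned.
  pending <- network$nodes
  repeat {
    progressed <- FALSE
    for (k in names(pending)) {
      nd <- pending[[k]]
      if (length(nd$outof) == 0) { pending[[k]] <- NULL; next }
      if (length(nd$into) == 0 || anyNA(flows[nd$into])) next
      q_in <- sum(flows[nd$into])
      ids <- nd$outof
      w <- split_weights(ids, segs, len, area, config$split_rule)
      flows[ids] <- q_in * w
      pending[[k]] <- NULL
      progressed <- TRUE
    }
    if (length(pending) == 0 || !progressed) break
  }
  if (anyNA(flows)) {
    stop("flow_split: unassigned segment(s) ",
         paste(names(flows)[is.na(flows)], collapse = ", "),
         " (disconnected from the inlet)", call. = FALSE)
  }
  network$segments$flow_ml_min <- unname(flows[network$segments$id])
  network
}

split_weights <- function(ids, segs, len, area, rule) {
  if (length(ids) == 1) return(1)
  a <- area[ids]
  equal_area <- diff(range(a)) <= 1e-12 * max(a)
  if (rule == "symmetric" || equal_area) {
    # equal mean velocity across daughters: Q_i proportional to A_i
    return(a / sum(a))
  }
  w <- segs$width_um[match(ids, segs$id)] * 1e-6
  h <- segs$height_um[match(ids, segs$id)] * 1e-6
  r <- (len[ids] * 1e-3) / (w^3 * h)
  g <- 1 / r
  g / sum(g)
}

#' Per-segment mean velocities
#'
#' @param network A [channel_network()] with flows assigned.
#' @return A tibble with one row per segment: id, geometry, flow, area and
#'   mean velocity (mm/s).
#' @export
segment_velocities <- function(network) {
  segs <- network$segments
  if (anyNA(segs$flow_ml_min)) {
    stop("segment_velocities: flows not assigned; call flow_split() first",
         call. = FALSE)
  }
  area <- cross_section_area(segs$width_um, segs$height_um)
  dplyr::mutate(segs,
    length_mm = segment_lengths(segs),
    area_m2 = area,
    mean_v_mm_s = expected_velocity(segs$flow_ml_min, area)
  )
}

# Project points onto each segment; returns per-point containing segment index
# (NA outside), arc position s (mm), signed lateral offset u in [-1, 1].
locate_points <- function(network, x, z) {
  segs <- network$segments
  n <- length(x)
  seg_idx <- rep(NA_integer_, n)
  s_out <- rep(NA_real_, n)
  u_out <- rep(NA_real_, n)
  best_u <- rep(Inf, n)
  for (i in seq_len(nrow(segs))) {
    dx <- segs$x1[i] - segs$x0[i]; dz <- segs$z1[i] - segs$z0[i]
    len <- sqrt(dx^2 + dz^2)
    ax <- dx / len; az <- dz / len
    px <- x - segs$x0[i]; pz <- z - segs$z0[i]
    s <- px * ax + pz * az
    d <- -px * az + pz * ax          # signed lateral distance, mm
    half_w <- segs$width_um[i] / 2000
    inside <- s >= -1e-12 & s <= len + 1e-12 & abs(d) <= half_w + 1e-12
    u <- d / half_w
    take <- inside & abs(u) < best_u
    seg_idx[take] <- i
    s_out[take] <- pmin(pmax(s[take], 0), len)
    u_out[take] <- pmin(pmax(u[take], -1), 1)
    best_u[take] <- abs(u[take])
  }
  list(segment = seg_idx, s = s_out, u = u_out)
}

#' Local flow velocity at a point
#'
#' Evaluates the ground-truth velocity vector at planar coordinates inside the
#' network. Across the imaged width the profile is a plane-Poiseuille
#' parabola, v(u) = 1.5 V_mean (1 - u^2), where u in [-1, 1] is the lateral
#' offset as a fraction of the half-width; the unimaged height dimension is
#' absorbed into the mean. Velocity is zero at the walls (no slip).
#'
#' @param network A [channel_network()] with flows assigned.
#' @param x,z Planar coordinates, mm (vectorised).
#' @return A tibble with one row per point: `segment` (NA outside the
#'   network), `vx`, `vz` and `speed_mm_s` (0 outside).
#' @export
local_velocity <- function(network, x, z) {
  sv <- segment_velocities(network)
  loc <- locate_points(network, x, z)
  vx <- vz <- speed <- rep(0, length(x))
  inside <- !is.na(loc$segment)
  if (any(inside)) {
    i <- loc$segment[inside]
    len <- sv$length_mm[i]
    ax <- (sv$x1[i] - sv$x0[i]) / len
    az <- (sv$z1[i] - sv$z0[i]) / len
    sp <- 1.5 * sv$mean_v_mm_s[i] * (1 - loc$u[inside]^2)
    vx[inside] <- sp * ax
    vz[inside] <- sp * az
    speed[inside] <- sp
  }
  tibble::tibble(
    x = x, z = z,
    segment = ifelse(inside, sv$id[loc$segment], NA_character_),
    vx = vx, vz = vz, speed_mm_s = speed
  )
}

#' Flux-weighted mean bubble speed for a plane-Poiseuille channel
#'
#' Particles entering in proportion to the local flux sample fast streamlines
#' more often; the mean speed over particles is
#' \eqn{\int v^2 du / \int v du = 1.2 V_{mean}} for the parabolic profile.
#'
#' @param mean_v_mm_s Channel mean velocity, mm/s.
#' @return Flux-weighted mean particle speed, mm/s.
#' @export
flux_weighted_mean_speed <- function(mean_v_mm_s) 1.2 * mean_v_mm_s

#' Rasterise the channel network to a pixel mask
#'
#' @param network A [channel_network()].
#' @param nrow,ncol Grid size in pixels (rows index depth z, columns lateral x).
#' @param origin Length-2 numeric, mm coordinates (x, z) of the centre of
#'   pixel (1, 1).
#' @param pitch_mm Pixel pitch, mm.
#' @param segments Optional character vector of segment ids; when given, only
#'   those segments are rasterised (e.g. the one vessel passing through a
#'   saturation ROI).
#' @return A logical matrix, TRUE inside any (selected) channel segment.
#' @export
channel_mask <- function(network, nrow, ncol, origin, pitch_mm,
                         segments = NULL) {
  segs <- network$segments
  if (!is.null(segments)) {
    segs <- segs[segs$id %in% segments, ]
    if (nrow(segs) == 0) {
      stop("channel_mask: no matching segments", call. = FALSE)
    }
  }
  x <- origin[1] + (seq_len(ncol) - 1) * pitch_mm
  z <- origin[2] + (seq_len(nrow) - 1) * pitch_mm
  g <- expand.grid(z = z, x = x)   # row index varies fastest, column-major
  loc <- locate_points(list(segments = segs), g$x, g$z)
  matrix(!is.na(loc$segment), nrow = nrow, ncol = ncol)
}

# Bounding box of the channel outlines (mm), including half-widths.
network_bbox <- function(network) {
  segs <- network$segments
  hw <- segs$width_um / 2000
  list(
    x = range(c(segs$x0 - hw, segs$x0 + hw, segs$x1 - hw, segs$x1 + hw)),
    z = range(c(segs$z0 - hw, segs$z0 + hw, segs$z1 - hw, segs$z1 + hw))
  )
}

# Origin (mm of pixel (1,1) centre) that centres the network in an
# nrow x ncol grid.
centered_origin <- function(network, nrow, ncol, pitch_mm) {
  bb <- network_bbox(network)
  c(mean(bb$x) - (ncol - 1) / 2 * pitch_mm,
    mean(bb$z) - (nrow - 1) / 2 * pitch_mm)
}

#' Write / read a network as a YAML file
#'
#' The serialisation lists each segment with its endpoints (mm), width and
#' height (um) and any assigned flow rate (mL/min).
#'
#' @param network A [channel_network()].
#' @param path File path.
#' @return `read_network()` returns a [channel_network()];
#'   `write_network()` returns `path` invisibly.
#' @export
write_network <- function(network, path) {
  segs <- network$segments
  yaml::write_yaml(list(segments = lapply(seq_len(nrow(segs)), function(i) {
    as.list(segs[i, ])
  })), path, precision = 15)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- yaml::read_yaml(path)
  segs <- dplyr::bind_rows(lapply(obj$segments, tibble::as_tibble))
  channel_network(segs)
}
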