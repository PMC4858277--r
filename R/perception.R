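#' Build the sensory input vector of a hunter
#'
#' Concatenates the 12 proximity activations, the 4 camera values of each
#' of the 12 rays (two type bits, a proximity value, a presence bit) and a
#' constant bias input of 1 — 61 values in `[0, 1]` for the default body.
#'
#' Proximity sensors sit at angles `heading + k * 360 / n_proximity`
#' degrees and report `max(0, 1 - d / proximity_range)` where `d` is the
#' distance from the body surface to the nearest obstacle (wall or agent)
#' along the sensor ray. Camera rays are evenly spaced across the field of
#' view centred on the heading; each reports the first agent disk it
#' intersects with type code none = (0,0), hunter = (0,1), hare = (1,0),
#' stag = (1,1), proximity `max(0, 1 - d / diag)` normalised by the arena
#' diagonal (camera rays have unbounded range), and a presence bit that
#' distinguishes "no target" from "far target". A ray that reaches the
#' wall reports type (0,0) and presence 0 but still carries the wall
#' proximity.
#'
#' @param world A [world_state()].
#' @param hunter_id Row index (1 or 2) of the perceiving hunter.
#' @return Numeric vector of length `n_proximity + 4 * n_camera_rays + 1`.
#' @export
build_input_vector <- function(world, hunter_id = 1L) {
  cpp_input_vector(as.integer(hunter_id) - 1L,
                   world$agents$x, world$agents$y,
                   ifelse(is.na(world$agents$heading[1:2]), 0,
                          world$agents$heading[1:2]),
                   kind_to_code(world$agents$kind),
                   cpp_config(world$config))
}

#' @rdname build_input_vector
#' @param sensor_index Proximity sensor index, 1-based; sensor `k` points
#'   at `heading + (k - 1) * 360 / n_proximity` degrees.
#' @return `proximity_activation()`: a single activation in `[0, 1]`.
#' @export
proximity_activation <- function(world, hunter_id, sensor_index) {
  stopifnot(sensor_index >= 1,
            sensor_index <= world$config$body$n_proximity)
  build_input_vector(world, hunter_id)[sensor_index]
}

#' @rdname build_input_vector
#' @param ray_index Camera ray index, 1-based, from the clockwise-most
#'   edge of the cone.
#' @return `camera_ray_values()`: the named quadruple
#'   `c(type1, type2, proximity, presence)`.
#' @export
camera_ray_values <- function(world, hunter_id, ray_index) {
  np <- world$config$body$n_proximity
  stopifnot(ray_index >= 1, ray_index <= world$config$body$n_camera_rays)
  v <- build_input_vector(world, hunter_id)
  quad <- v[np + (ray_index - 1L) * 4L + 1:4]
  names(quad) <- c("type1", "type2", "proximity", "presence")
  quad
}

#' Angles of the camera rays relative to the heading
#'
#' Rays are evenly spaced across the field of view with half-step offsets,
#' so the two central rays straddle the heading symmetrically.
#'
#' @param body A [body_spec()].
#' @return Offsets in radians, length `n_camera_rays`.
#' @export
camera_ray_offsets <- function(body = body_spec()) {
  fov <- body$camera_fov * pi / 180
  -fov / 2 + fov * (seq_len(body$n_camera_rays) - 0.5) / body$n_camera_rays
}
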