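#' Deterministic hand-placed test worlds
#'
#' A catalogue of fixed arena scenarios used to unit-test perception,
#' capture and collision code with pen-and-paper geometry:
#'
#' * `"hunter-facing-stag-at-50"` — hunter 1 at the arena centre heading
#'   along +x, a stag 50 units ahead (centre to centre); hunter 2 parked
#'   far away in a corner region. The central camera rays see the stag.
#' * `"two-hunters-flanking-prey"` — both hunters 20 units from a hare on
#'   opposite sides, both inside catching distance; held in place this
#'   produces a cooperative capture.
#' * `"two-hunters-flanking-stag"` — same geometry around a stag.
#' * `"one-hunter-near-hare"` — only hunter 1 inside catching distance of
#'   a hare; hunter 2 far away. Produces a solitary capture.
#' * `"corner-trap"` — hunter 1 near the arena origin corner heading
#'   into it; driving forward clamps the centre at (radius, radius).
#'
#' @param scenario_name One of the catalogue names.
#' @param config A [staghunt_config()] (geometry only; prey counts in the
#'   fixture override the configured composition).
#' @return A [world_state()].
#' @export
build_fixture <- function(scenario_name, config = staghunt_config()) {
  w <- config$arena$width
  h <- config$arena$height
  cx <- w / 2
  cy <- h / 2
  agents <- switch(
    scenario_name,
    "hunter-facing-stag-at-50" = tibble::tibble(
      kind = c("hunter", "hunter", "stag"),
      x = c(cx, w / 8, cx + 50),
      y = c(cy, h / 8, cy),
      heading = c(0, 0, NA)),
    "two-hunters-flanking-prey" = tibble::tibble(
      kind = c("hunter", "hunter", "hare"),
      x = c(cx - 20, cx + 20, cx),
      y = c(cy, cy, cy),
      heading = c(0, pi, NA)),
    "two-hunters-flanking-stag" = tibble::tibble(
      kind = c("hunter", "hunter", "stag"),
      x = c(cx - 20, cx + 20, cx),
      y = c(cy, cy, cy),
      heading = c(0, pi, NA)),
    "one-hunter-near-hare" = tibble::tibble(
      kind = c("hunter", "hunter", "hare"),
      x = c(cx - 20, w / 8, cx),
      y = c(cy, h / 8, cy),
      heading = c(0, 0, NA)),
    "corner-trap" = tibble::tibble(
      kind = c("hunter", "hunter"),
      x = c(20, cx),
      y = c(20, cy),
      heading = c(atan2(-1, -1), 0)),
    stop("unknown fixture scenario '", scenario_name, "'", call. = FALSE)
  )
  world_state(agents, config)
}
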