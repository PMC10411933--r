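#' Workspace geometry for the aiming task
#'
#' The task takes place on a circular target plane viewed either in the
#' *Point* context (mouse deltas translate a cursor over a static scene) or
#' the *Look* context (mouse deltas pan/tilt a first-person camera while the
#' cursor stays at screen centre). All lengths are in arbitrary units (au),
#' the workspace length scale: the scene is 4 au tall and the target plane
#' 3 au in diameter. Plane coordinates have their origin at the plane centre,
#' x rightward, y upward; angles are measured counterclockwise from +x, so
#' 0 deg is a target directly right.
#'
#' @param scene_height Height of the visible scene, au.
#' @param plane_diameter Diameter of the circular target plane, au.
#' @param start_diameter Diameter of the central start point, au.
#' @param cursor_diameter Diameter of the cursor, au.
#' @param target_diameter Diameter of a target, au.
#' @param snap_radius Homing-phase auto-aim radius around the start point, au.
#' @param fov_vertical Vertical field of view of the Look camera, degrees.
#'   Used to place the camera so the scene height exactly fills the view when
#'   `plane_distance` is not given.
#' @param plane_distance Distance from the Look camera to the target plane,
#'   au. Defaults to `scene_height / 2 / tan(fov_vertical / 2)` so that the
#'   plane subtends the full scene height.
#' @param gain Cursor displacement in au per normalised device count.
#'
#' @return A list of class `scene_config`.
#' @examples
#' cfg <- scene_config()
#' cfg$plane_distance
#' @export
scene_config <- function(scene_height = 4, plane_diameter = 3,
                         start_diameter = 0.1, cursor_diameter = 0.15,
                         target_diameter = 0.2, snap_radius = 0.05,
                         fov_vertical = 60, plane_distance = NULL,
                         gain = 1) {
  plane_distance <- plane_distance %||%
    (scene_height / 2 / tan(deg2rad(fov_vertical / 2)))
  cfg <- list(
    scene_height = scene_height, plane_diameter = plane_diameter,
    start_diameter = start_diameter, cursor_diameter = cursor_diameter,
    target_diameter = target_diameter, snap_radius = snap_radius,
    fov_vertical = fov_vertical, plane_distance = plane_distance,
    gain = gain
  )
  lens <- unlist(cfg[c("scene_height", "plane_diameter", "start_diameter",
                       "cursor_diameter", "target_diameter", "snap_radius",
                       "plane_distance", "gain")])
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    abort("all scene lengths must be finite and strictly positive")
  }
  if (target_diameter >= plane_diameter) {
    abort("target_diameter must be smaller than plane_diameter")
  }
  if (snap_radius >= start_diameter * 2) {
    # snap radius is meant to be a tight auto-aim zone around the start point
    warn("snap_radius is large relative to the start point")
  }
  structure(cfg, class = "scene_config")
}

#' Advance the cursor by one device delta (Point context)
#'
#' One step of the Point-context mapping: the cursor translates by
#' `gain * delta` with no clamping to the plane.
#'
#' @param cursor Length-2 numeric, current cursor position (au).
#' @param delta Length-2 numeric, device counts moved since the last sample.
#' @param cfg A [scene_config()].
#' @return Length-2 numeric, the new cursor position.
#' @examples
#' point_step(c(0.2, 0.1), c(0.1, -0.1), scene_config())
#' @export
point_step <- function(cursor, delta, cfg = scene_config()) {
  if (length(delta) != 2 || any(!is.finite(delta))) {
    abort("delta must be two finite numbers")
  }
  cursor + cfg$gain * delta
}

#' Camera pose whose central ray hits a virtual cursor (Look context)
#'
#' In the Look context the cursor stays at screen centre and the camera
#' pans/tilts. The two contexts are equated constructively: a single virtual
#' cursor lives in plane coordinates, and the Look camera is posed so that
#' its central ray intersects the target plane exactly at that cursor. The
#' pose is therefore `yaw = atan(x / plane_distance)`,
#' `pitch = atan(y / plane_distance)`.
#'
#' @param virtual_cursor Length-2 numeric, plane coordinates (au).
#' @param cfg A [scene_config()].
#' @return A list with `yaw` and `pitch` in degrees (|yaw|, |pitch| < 90).
#' @examples
#' look_pose_for_cursor(c(1, 0), scene_config(plane_distance = 2))
#' @export
look_pose_for_cursor <- function(virtual_cursor, cfg = scene_config()) {
  if (any(!is.finite(virtual_cursor))) abort("virtual_cursor must be finite")
  yaw <- rad2deg(atan(virtual_cursor[1] / cfg$plane_distance))
  pitch <- rad2deg(atan(virtual_cursor[2] / cfg$plane_distance))
  if (abs(yaw) >= 90 || abs(pitch) >= 90) {
    abort("camera pose beyond +/-90 degrees")
  }
  list(yaw = yaw, pitch = pitch)
}

#' Plane point hit by a camera pose's central ray
#'
#' Inverse of [look_pose_for_cursor()]: intersect the central ray of a
#' yaw/pitch pose with the target plane.
#'
#' @param pose List with `yaw` and `pitch` in degrees.
#' @param cfg A [scene_config()].
#' @return Length-2 numeric plane coordinates (au).
#' @export
cursor_for_look_pose <- function(pose, cfg = scene_config()) {
  if (abs(pose$yaw) >= 90 || abs(pose$pitch) >= 90) {
    abort("camera pose beyond +/-90 degrees")
  }
  c(cfg$plane_distance * tan(deg2rad(pose$yaw)),
    cfg$plane_distance * tan(deg2rad(pose$pitch)))
}

#' Map a device-delta trace to the analysis-space cursor path
#'
#' Integrates a stream of timestamped device deltas into plane coordinates.
#' By construction the returned path is identical in both contexts given
#' identical deltas: Look is a rendering transform of the same underlying
#' virtual cursor, so context matters only for rendering (and for the
#' synthetic performer's behaviour), never for analysis.
#'
#' @param trace Data frame with columns `t_ms`, `dx`, `dy` (device counts),
#'   timestamps strictly increasing.
#' @param context `"point"` or `"look"`. Kept for interface symmetry; the
#'   output does not depend on it.
#' @param cfg A [scene_config()].
#' @param start Length-2 numeric, starting cursor position (au).
#' @return A tibble with columns `t_ms`, `x`, `y`; the first row is the start
#'   position at the time of the first sample (or an empty-trace path of just
#'   the start position at t = 0).
#' @examples
#' tr <- tibble::tibble(t_ms = c(16, 32, 48), dx = c(0.5, 0.3, 0.2), dy = 0)
#' effective_cursor_path(tr, "look")
#' @export
effective_cursor_path <- function(trace, context = c("point", "look"),
                                  cfg = scene_config(), start = c(0, 0)) {
  context <- match.arg(tolower(context), c("point", "look"))
  if (nrow(trace) == 0) {
    return(tibble(t_ms = 0, x = start[1], y = start[2]))
  }
  if (is.unsorted(trace$t_ms, strictly = TRUE)) {
    abort("trace timestamps must be strictly increasing")
  }
  if (any(!is.finite(trace$dx)) || any(!is.finite(trace$dy))) {
    abort("deltas must be finite")
  }
  tibble(
    t_ms = trace$t_ms,
    x = start[1] + cfg$gain * cumsum(trace$dx),
    y = start[2] + cfg$gain * cumsum(trace$dy)
  )
}

#' Homing-phase auto-aim snap
#'
#' During the pre-trial homing state the cursor snaps to the start point when
#' within the snap radius (boundary inclusive: a cursor exactly at the snap
#' radius snaps).
#'
#' @param cursor Length-2 numeric cursor position (au).
#' @param cfg A [scene_config()].
#' @param start Length-2 numeric, the start point (plane centre).
#' @return Length-2 numeric: `start` if within the snap radius, else `cursor`.
#' @examples
#' snap_to_start(c(0.03, 0))
#' snap_to_start(c(0.06, 0))
#' @export
snap_to_start <- function(cursor, cfg = scene_config(), start = c(0, 0)) {
  if (sqrt(sum((cursor - start)^2)) <= cfg$snap_radius) start else cursor
}
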