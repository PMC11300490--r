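# MOT trial kinematics: 8 spheres wandering in a cubic volume for 8 s.
# Trajectories make trial logs replayable and realistic; trial *outcomes*
# are generated by the psychometric observer, which depends only on speed
# and load, so the kinematics are decoupled from scoring.

#' Initialize an MOT trial scene
#'
#' Places `n_objects` non-overlapping spheres uniformly in the unit cube and
#' marks `load` of them as targets. Speeds in cm/s are mapped to cube units
#' through `cube_cm` (the physical edge length the unit cube represents).
#'
#' @param load Number of targets (1--4).
#' @param speed_cms Object speed, cm/s.
#' @param n_objects Number of objects (default 8).
#' @param min_sep Minimum pairwise separation at initialization (cube units).
#' @param cube_cm Physical cube edge, cm (speed scale; default 100).
#' @param dt Timestep, s.
#' @param duration Movement duration, s (default 8).
#' @param perturb_sd SD of the per-step Gaussian heading perturbation.
#' @return A list of class `"mot_scene"` with positions (n x 3), unit
#'   headings (n x 3), `target_indices`, and the motion parameters.
#' @export
init_scene <- function(load, speed_cms = 68, n_objects = 8, min_sep = 0.15,
                       cube_cm = 100, dt = 0.02, duration = 8,
                       perturb_sd = 0.15) {
  if (load < 1 || load > 4) stop("load must be between 1 and 4")
  stopifnot(speed_cms > 0, n_objects >= load, min_sep > 0, dt > 0)
  pos <- matrix(NA_real_, n_objects, 3)
  placed <- 0
  tries <- 0
  while (placed < n_objects) {
    cand <- stats::runif(3, min_sep / 2, 1 - min_sep / 2)
    ok <- placed == 0 ||
      all(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 3, byrow = TRUE))^2)) >= min_sep)
    if (ok) {
      placed <- placed + 1
      pos[placed, ] <- cand
    }
    tries <- tries + 1
    if (tries > 10000) stop("could not place objects with the requested separation")
  }
  h <- matrix(stats::rnorm(n_objects * 3), n_objects, 3)
  h <- h / sqrt(rowSums(h^2))
  structure(list(
    positions = pos, headings = h,
    target_indices = sort(sample.int(n_objects, load)),
    n_objects = n_objects, load = load, speed_cms = speed_cms,
    cube_cm = cube_cm, dt = dt, duration = duration,
    min_sep = min_sep, perturb_sd = perturb_sd, time = 0
  ), class = "mot_scene")
}

#' Advance a scene by one timestep
#'
#' Constant-magnitude motion with a small random heading perturbation,
#' specular reflection at the cube faces, and a short-range repulsion that
#' turns headings of near-overlapping pairs away from each other. Speed
#' magnitude is conserved exactly (headings are renormalized every step).
#'
#' @param scene A `mot_scene`.
#' @return The updated scene.
#' @export
step_scene <- function(scene) {
  h <- scene$headings
  n <- scene$n_objects
  if (scene$perturb_sd > 0) {
    h <- h + matrix(stats::rnorm(n * 3, 0, scene$perturb_sd), n, 3)
  }
  # pairwise repulsion: steer apart anything closer than min_sep
  d <- as.matrix(stats::dist(scene$positions))
  close <- which(d < scene$min_sep & upper.tri(d), arr.ind = TRUE)
  if (nrow(close)) {
    for (r in seq_len(nrow(close))) {
      i <- close[r, 1]; j <- close[r, 2]
      away <- scene$positions[i, ] - scene$positions[j, ]
      nrm <- sqrt(sum(away^2))
      if (nrm < 1e-12) away <- stats::rnorm(3) else away <- away / nrm
      h[i, ] <- h[i, ] + away
      h[j, ] <- h[j, ] - away
    }
  }
  h <- h / sqrt(rowSums(h^2))
  step_units <- scene$speed_cms / scene$cube_cm * scene$dt
  p <- scene$positions + h * step_units
  # specular reflection, repeated in case a large step crosses twice
  for (k in 1:3) {
    repeat {
      below <- p[, k] < 0
      above <- p[, k] > 1
      if (!any(below | above)) break
      p[below, k] <- -p[below, k]
      h[below, k] <- abs(h[below, k])
      p[above, k] <- 2 - p[above, k]
      h[above, k] <- -abs(h[above, k])
    }
  }
  scene$positions <- p
  scene$headings <- h
  scene$time <- scene$time + scene$dt
  scene
}

#' Run a full trial's kinematics
#'
#' Steps the scene for `duration / dt` steps and returns the trajectory in
#' long format, suitable for a trial log.
#'
#' @param scene A `mot_scene` from [init_scene()].
#' @return A list with the final `scene` and a `trajectory` data.frame:
#'   `t`, `object_id`, `x`, `y`, `z`, `is_target`.
#' @export
run_scene <- function(scene) {
  n_steps <- round(scene$duration / scene$dt)
  n <- scene$n_objects
  out <- vector("list", n_steps + 1)
  snap <- function(s) data.frame(
    t = s$time, object_id = seq_len(n),
    x = s$positions[, 1], y = s$positions[, 2], z = s$positions[, 3],
    is_target = seq_len(n) %in% s$target_indices
  )
  out[[1]] <- snap(scene)
  for (s in seq_len(n_steps)) {
    scene <- step_scene(scene)
    out[[s + 1]] <- snap(scene)
  }
  list(scene = scene, trajectory = do.call(rbind, out))
}
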