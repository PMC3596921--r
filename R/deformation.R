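# Mask-controlled mass-spring deformation. Mesh vertices become particles,
# mesh edges become springs; per-particle masses come from a grayscale mask
# map so that darker regions accelerate (and curl) more. Integration is
# explicit Euler with a velocity constraint that caps spring stretch at
# (1 + tau_c) times rest length.

#' Grayscale mask map
#'
#' An 8-bit single-channel image whose pixel intensities set particle
#' masses. Stored as an integer matrix in image convention: row 1 is the top
#' row, and texture coordinate v = 0 addresses the bottom row.
#'
#' @param pixels Numeric or integer matrix with values in 0..255.
#' @return An object of class `mask_map` with `pixels`, `width`, `height`.
#' @export
mask_map <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (length(pixels) < 1 || any(!is.finite(pixels)) ||
      any(pixels < 0) || any(pixels > 255) || any(pixels != round(pixels))) {
    stop("mask pixels must be integers in [0, 255] with at least one pixel",
         call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, width = ncol(pixels), height = nrow(pixels)),
            class = "mask_map")
}

#' Look up mask grayscale values at texture coordinates
#'
#' Nearest-pixel lookup with the uv origin at the image's lower-left corner.
#'
#' @param mask A [mask_map()].
#' @param uv n x 2 matrix of texture coordinates in `[0, 1]^2`.
#' @return Integer vector of grayscale values in 0..255.
#' @export
mask_value <- function(mask, uv) {
  stopifnot(inherits(mask, "mask_map"))
  uv <- as.matrix(uv)
  if (ncol(uv) != 2 || any(!is.finite(uv)) || any(uv < 0) || any(uv > 1)) {
    stop("uv coordinates must lie in [0, 1]^2", call. = FALSE)
  }
  w <- mask$width
  h <- mask$height
  col <- pmin(floor(uv[, 1] * w), w - 1L) + 1L
  row <- h - pmin(floor(uv[, 2] * h), h - 1L)
  mask$pixels[cbind(row, col)]
}

#' Map grayscale values to particle masses
#'
#' A grayscale value of 0 maps to mass 0.5; any other value `g` maps to
#' `log(g + 1)` (natural logarithm). The logarithm makes mass vary more
#' gently than the raw intensities; the explicit 0.5 branch avoids the
#' massless particle `log(1) = 0` would produce. Masses are therefore
#' non-decreasing in gray, within `[0.5, log(256)]`.
#'
#' @param gray Integer vector of grayscale values in 0..255.
#' @return Numeric vector of masses.
#' @export
mass_from_gray <- function(gray) {
  if (any(!is.finite(gray)) || any(gray < 0) || any(gray > 255)) {
    stop("gray values must lie in 0..255", call. = FALSE)
  }
  ifelse(gray == 0, 0.5, log(gray + 1))
}

#' Assign particle masses from a mask map
#'
#' Looks up each vertex's mask pixel at its texture coordinates and applies
#' the gray-to-mass mapping of [mass_from_gray()].
#'
#' @param mesh A [tri_mesh()] with uv coordinates in `[0, 1]^2`.
#' @param mask A [mask_map()].
#' @return Numeric vector of per-vertex masses.
#' @export
mass_from_mask <- function(mesh, mask) {
  stopifnot(inherits(mesh, "tri_mesh"))
  mass_from_gray(mask_value(mask, mesh$uv))
}

#' Build spring constraints from mesh connectivity
#'
#' One constraint per unique undirected mesh edge, built by the flag
#' traversal: particles are visited in index order; each visited particle
#' adds constraints to those of its adjacent particles (vertices sharing a
#' triangle) that have not been traversed yet, then is flagged as traversed.
#' Every edge is thus created exactly once. Rest lengths are the edge
#' lengths of the undeformed mesh.
#'
#' @param mesh A [tri_mesh()].
#' @return A data frame with columns `u`, `v` (particle indices) and
#'   `rest_length`.
#' @export
build_constraints <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  tris <- mesh$triangles
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  pairs <- rbind(tris[, c(1, 2), drop = FALSE],
                 tris[, c(2, 3), drop = FALSE],
                 tris[, c(3, 1), drop = FALSE])
  pairs <- rbind(pairs, pairs[, c(2, 1), drop = FALSE])
  sp <- split(pairs[, 2], pairs[, 1])
  for (nm in names(sp)) adj[[as.integer(nm)]] <- unique(sp[[nm]])
  traversed <- rep(FALSE, n)
  us <- integer(0)
  vs <- integer(0)
  for (i in seq_len(n)) {
    nb <- adj[[i]]
    nb <- nb[!traversed[nb]]
    if (length(nb)) {
      us <- c(us, rep.int(i, length(nb)))
      vs <- c(vs, nb)
    }
    traversed[i] <- TRUE
  }
  V <- mesh$vertices
  rest <- sqrt(rowSums((V[us, , drop = FALSE] - V[vs, , drop = FALSE])^2))
  data.frame(u = us, v = vs, rest_length = rest)
}

#' Uniform external force field
#'
#' Convenience constructor for a constant force applied to every particle
#' (e.g. `c(0, 0, -1)` for a downward pull out of the leaf plane).
#'
#' @param force Length-3 numeric force vector.
#' @param until Optional time after which the force switches off.
#' @return A function `f(positions, t)` returning an n x 3 force matrix.
#' @export
uniform_force <- function(force = c(0, 0, -1), until = Inf) {
  force <- as.numeric(force)
  stopifnot(length(force) == 3, all(is.finite(force)))
  function(positions, t) {
    n <- nrow(positions)
    if (t <= until) {
      matrix(force, n, 3, byrow = TRUE)
    } else {
      matrix(0, n, 3)
    }
  }
}

#' Simulation configuration for the mass-spring model
#'
#' @param dt Time step (must be small enough for stable explicit Euler;
#'   default 0.005).
#' @param tau_c Deformation threshold: maximum allowed fractional spring
#'   elongation beyond rest length (default 0.1, i.e. 10 percent).
#' @param stiffness Linear spring constant per unit extension (default 50).
#' @param damping Velocity-proportional damping coefficient (default 0.1).
#' @param external_force Function `f(positions, t)` returning an n x 3 force
#'   matrix; default is a uniform unit downward force from [uniform_force()].
#' @param n_constraint_passes Maximum number of velocity-constraint sweeps
#'   per time step; sweeps stop as soon as a full sweep finds no spring
#'   over its bound. The default (2000) is a safety cap, not a typical
#'   count: most steps need a handful of sweeps, while heavily loaded
#'   configurations can need a few hundred for the corrections to propagate
#'   across the spring network.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 0.005, tau_c = 0.1, stiffness = 50,
                       damping = 0.1, external_force = uniform_force(),
                       n_constraint_passes = 2000L) {
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (!is.numeric(tau_c) || tau_c < 0) stop("tau_c must be >= 0", call. = FALSE)
  if (!is.numeric(damping) || damping < 0) {
    stop("damping must be >= 0", call. = FALSE)
  }
  if (!is.function(external_force)) {
    stop("external_force must be a function(positions, t)", call. = FALSE)
  }
  if (n_constraint_passes < 1) {
    stop("n_constraint_passes must be a positive integer", call. = FALSE)
  }
  structure(list(dt = dt, tau_c = tau_c, stiffness = stiffness,
                 damping = damping, external_force = external_force,
                 n_constraint_passes = as.integer(n_constraint_passes)),
            class = "sim_config")
}

#' Particle system state
#'
#' @param positions n x 3 (or n x 2, lifted with z = 0) matrix of particle
#'   positions.
#' @param masses Positive per-particle masses.
#' @param fixed Logical vector of anchored particles (e.g. the petiole);
#'   fixed particles keep zero velocity and acceleration for all time.
#' @return An object of class `particle_system` with positions, velocities,
#'   accelerations, masses and fixed flags.
#' @export
particle_system <- function(positions, masses, fixed = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) == 2) positions <- cbind(positions, 0)
  if (ncol(positions) != 3 || !all(is.finite(positions))) {
    stop("positions must be an n x 3 (or n x 2) finite matrix", call. = FALSE)
  }
  n <- nrow(positions)
  masses <- as.numeric(masses)
  if (length(masses) != n || any(!is.finite(masses)) || any(masses <= 0)) {
    stop("each particle needs a positive finite mass", call. = FALSE)
  }
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  if (length(fixed) != n) {
    stop("fixed flags must have one entry per particle", call. = FALSE)
  }
  structure(list(positions = positions,
                 velocities = matrix(0, n, 3),
                 accelerations = matrix(0, n, 3),
                 masses = masses,
                 fixed = as.logical(fixed)),
            class = "particle_system")
}

# Net force on every particle: Hooke springs along the constraints,
# velocity-proportional damping, plus the external field.
net_forces <- function(ps, constraints, config, t) {
  P <- ps$positions
  frc <- config$external_force(P, t) - config$damping * ps$velocities
  if (nrow(constraints) > 0) {
    d <- P[constraints$v, , drop = FALSE] - P[constraints$u, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len == 0] <- .Machine$double.eps
    fmag <- config$stiffness * (len - constraints$rest_length) / len
    f <- d * fmag  # pull u toward v when stretched
    idx <- c(constraints$u, constraints$v)
    contrib <- rbind(f, -f)
    agg <- rowsum(contrib, group = idx)
    rows <- as.integer(rownames(agg))
    frc[rows, ] <- frc[rows, ] + agg
  }
  frc
}

#' One explicit Euler step
#'
#' Updates the particle system in the order: acceleration from the forces at
#' time `t` divided by mass; velocity from the new acceleration; position
#' from the new velocity. Fixed particles are left untouched.
#'
#' @param particles A [particle_system()].
#' @param constraints Spring constraints from [build_constraints()] (may
#'   have zero rows).
#' @param config A [sim_config()].
#' @param t Current simulation time (passed to the external force field).
#' @return The updated `particle_system`.
#' @export
euler_step <- function(particles, constraints, config, t = 0) {
  stopifnot(inherits(particles, "particle_system"),
            inherits(config, "sim_config"))
  frc <- net_forces(particles, constraints, config, t)
  if (any(!is.finite(frc))) {
    bad <- which(rowSums(!is.finite(frc)) > 0)[1]
    stop(sprintf("numerical instability: non-finite force on particle %d", bad),
         call. = FALSE)
  }
  a <- frc / particles$masses
  a[particles$fixed, ] <- 0
  v <- particles$velocities + config$dt * a
  v[particles$fixed, ] <- 0
  particles$accelerations <- a
  particles$velocities <- v
  particles$positions <- particles$positions + config$dt * v
  particles
}

# Sweep the constraints in ascending index order, correcting relative
# velocities so each spring's predicted next length lands at most at
# (1 + tau_c) * rest_length. Sweeps repeat until one is clean (the pass
# budget is a safety cap): corrections to one spring can re-violate its
# neighbours, and the post-step bound only holds once a full sweep finds no
# offender. Flat per-axis vectors keep the sequential inner loop cheap.
constrain_velocities_core <- function(ps, constraints, config) {
  if (nrow(constraints) == 0) return(ps)
  dt <- config$dt
  lim <- (1 + config$tau_c) * constraints$rest_length
  fixed <- ps$fixed
  uu <- constraints$u
  vv <- constraints$v
  if (any(fixed[uu] & fixed[vv])) {
    both <- which(fixed[uu] & fixed[vv])
    rel <- ps$positions[vv[both], , drop = FALSE] -
      ps$positions[uu[both], , drop = FALSE]
    if (any(sqrt(rowSums(rel^2)) > lim[both] * (1 + 1e-12))) {
      stop("spring with two fixed endpoints violates its length bound",
           call. = FALSE)
    }
  }
  relx0 <- ps$positions[vv, 1] - ps$positions[uu, 1]
  rely0 <- ps$positions[vv, 2] - ps$positions[uu, 2]
  relz0 <- ps$positions[vv, 3] - ps$positions[uu, 3]
  vx <- ps$velocities[, 1]
  vy <- ps$velocities[, 2]
  vz <- ps$velocities[, 3]
  for (pass in seq_len(config$n_constraint_passes)) {
    predx <- relx0 + dt * (vx[vv] - vx[uu])
    predy <- rely0 + dt * (vy[vv] - vy[uu])
    predz <- relz0 + dt * (vz[vv] - vz[uu])
    plen <- sqrt(predx^2 + predy^2 + predz^2)
    viol <- which(plen > lim * (1 + 1e-12))
    if (!length(viol)) break
    for (k in viol) {
      i <- uu[k]
      j <- vv[k]
      dx <- relx0[k] + dt * (vx[j] - vx[i])
      dy <- rely0[k] + dt * (vy[j] - vy[i])
      dz <- relz0[k] + dt * (vz[j] - vz[i])
      l <- sqrt(dx * dx + dy * dy + dz * dz)
      if (l <= lim[k]) next
      s <- (1 - lim[k] / l) / dt
      cx <- dx * s
      cy <- dy * s
      cz <- dz * s
      if (fixed[i]) {
        vx[j] <- vx[j] - cx; vy[j] <- vy[j] - cy; vz[j] <- vz[j] - cz
      } else if (fixed[j]) {
        vx[i] <- vx[i] + cx; vy[i] <- vy[i] + cy; vz[i] <- vz[i] + cz
      } else {
        vx[j] <- vx[j] - cx / 2; vy[j] <- vy[j] - cy / 2; vz[j] <- vz[j] - cz / 2
        vx[i] <- vx[i] + cx / 2; vy[i] <- vy[i] + cy / 2; vz[i] <- vz[i] + cz / 2
      }
    }
  }
  ps$velocities <- cbind(vx, vy, vz, deparse.level = 0)
  ps
}

#' Constrain particle velocities against spring over-elasticity
#'
#' After tentative velocities have been computed, each spring's predicted
#' relative position one step ahead is tested against the elongation bound
#' `(1 + tau_c) * rest_length`. For an offending spring the relative
#' velocity component along the predicted axis is reduced so the predicted
#' length lands exactly on the bound; the correction is split equally
#' between two free endpoints, or taken entirely by the free endpoint when
#' the other is fixed. Constraints are processed in ascending index order
#' and sweeps repeat (up to `n_constraint_passes`) until none is violated.
#'
#' @inheritParams euler_step
#' @return The `particle_system` with corrected velocities.
#' @export
constrain_velocities <- function(particles, constraints, config) {
  stopifnot(inherits(particles, "particle_system"),
            inherits(config, "sim_config"))
  constrain_velocities_core(particles, constraints, config)
}

#' Total kinetic energy of a particle system
#'
#' @param particles A [particle_system()].
#' @return `0.5 * sum(m * |v|^2)`.
#' @export
kinetic_energy <- function(particles) {
  stopifnot(inherits(particles, "particle_system"))
  0.5 * sum(particles$masses * rowSums(particles$velocities^2))
}

#' Simulate mask-controlled leaf deformation
#'
#' Runs the full deformation procedure: particle masses are assigned from
#' the mask map, spring constraints built from the mesh edges, initial
#' velocities and accelerations set to zero, and the system integrated by
#' explicit Euler with per-step velocity constraints. Vertices within
#' `anchor_radius` of the petiole point are fixed.
#'
#' @param mesh A [tri_mesh()].
#' @param mask A [mask_map()].
#' @param config A [sim_config()].
#' @param n_steps Number of time steps (>= 0).
#' @param snapshot_every Interval (in steps) between stored snapshots;
#'   snapshot 0 is always the undeformed mesh and the final state is always
#'   included.
#' @param petiole Length-2 petiole anchor point; defaults to the boundary
#'   vertex with the smallest x coordinate.
#' @param anchor_radius Vertices within this distance of the petiole are
#'   fixed; defaults to 5 percent of the bounding-box diagonal (at least the
#'   single nearest vertex is always anchored).
#' @return An object of class `leaf_deformation`: `snapshots` (list of
#'   n x 3 position matrices, each with a `step` attribute), `mesh`,
#'   `masses`, `fixed`, final `particles`, a `log` data frame (step, maximum
#'   fractional elongation, kinetic energy) and `max_elongation`, the
#'   maximum fractional spring elongation observed over the whole run.
#' @export
simulate_deformation <- function(mesh, mask, config = sim_config(),
                                 n_steps = 500, snapshot_every = 100,
                                 petiole = NULL, anchor_radius = NULL) {
  stopifnot(inherits(mesh, "tri_mesh"), inherits(mask, "mask_map"),
            inherits(config, "sim_config"))
  if (n_steps < 0 || n_steps != round(n_steps)) {
    stop("n_steps must be a non-negative integer", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  V <- mesh$vertices
  if (is.null(petiole)) {
    bidx <- which(mesh$boundary)
    petiole <- V[bidx[which.min(V[bidx, 1])], ]
  }
  if (is.null(anchor_radius)) {
    anchor_radius <- 0.05 * sqrt((mesh$bbox[2] - mesh$bbox[1])^2 +
                                   (mesh$bbox[4] - mesh$bbox[3])^2)
  }
  dpet <- sqrt((V[, 1] - petiole[1])^2 + (V[, 2] - petiole[2])^2)
  fixed <- dpet <= anchor_radius
  if (!any(fixed)) fixed[which.min(dpet)] <- TRUE
  masses <- mass_from_mask(mesh, mask)
  ps <- particle_system(V, masses, fixed)
  constraints <- build_constraints(mesh)
  rest <- constraints$rest_length
  snapshots <- list(structure(ps$positions, step = 0L))
  log_steps <- integer(0)
  log_elong <- numeric(0)
  log_ke <- numeric(0)
  max_elong <- 0
  if (n_steps > 0) {
    for (step in seq_len(n_steps)) {
      t <- (step - 1L) * config$dt
      frc <- net_forces(ps, constraints, config, t)
      if (any(!is.finite(frc))) {
        bad <- which(rowSums(!is.finite(frc)) > 0)[1]
        stop(sprintf(
          "numerical instability: non-finite force on particle %d at step %d",
          bad, step), call. = FALSE)
      }
      a <- frc / ps$masses
      a[ps$fixed, ] <- 0
      ps$accelerations <- a
      ps$velocities <- ps$velocities + config$dt * a
      ps$velocities[ps$fixed, ] <- 0
      ps <- constrain_velocities_core(ps, constraints, config)
      ps$velocities[ps$fixed, ] <- 0
      ps$positions <- ps$positions + config$dt * ps$velocities
      len <- sqrt(rowSums((ps$positions[constraints$v, , drop = FALSE] -
                             ps$positions[constraints$u, , drop = FALSE])^2))
      elong <- max((len - rest) / rest)
      max_elong <- max(max_elong, elong)
      if (step %% snapshot_every == 0 && step < n_steps) {
        snapshots[[length(snapshots) + 1L]] <- structure(ps$positions,
                                                         step = step)
      }
      if (step %% 10L == 0 || step == n_steps) {
        log_steps <- c(log_steps, step)
        log_elong <- c(log_elong, elong)
        log_ke <- c(log_ke, kinetic_energy(ps))
      }
    }
    snapshots[[length(snapshots) + 1L]] <- structure(ps$positions,
                                                     step = n_steps)
  }
  structure(
    list(snapshots = snapshots, mesh = mesh, masses = masses, fixed = fixed,
         particles = ps,
         log = data.frame(step = log_steps, max_elongation = log_elong,
                          kinetic_energy = log_ke),
         max_elongation = max_elong),
    class = "leaf_deformation"
  )
}

#' @export
print.leaf_deformation <- function(x, ...) {
  cat(sprintf(
    "<leaf_deformation: %d particles (%d fixed), %d snapshots, max elongation %.4f>\n",
    nrow(x$particles$positions), sum(x$fixed), length(x$snapshots),
    x$max_elongation))
  invisible(x)
}
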