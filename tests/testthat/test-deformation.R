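test_that("constraint building yields one spring per unique edge", {
  tri <- tri_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1))
  expect_equal(nrow(build_constraints(tri)), 3L)

  two <- unit_square_mesh()
  cons <- build_constraints(two)
  expect_equal(nrow(cons), 5L)
  keys <- paste(pmin(cons$u, cons$v), pmax(cons$u, cons$v))
  expect_equal(anyDuplicated(keys), 0L)
  expect_true("1 3" %in% keys)  # the shared diagonal appears exactly once

  # against an independent set-based edge enumeration, on a real leaf mesh
  mf <- maple_fixture_mesh()
  cons <- build_constraints(mf$mesh)
  tris <- mf$mesh$triangles
  ekeys <- unique(c(paste(pmin(tris[, 1], tris[, 2]), pmax(tris[, 1], tris[, 2])),
                    paste(pmin(tris[, 2], tris[, 3]), pmax(tris[, 2], tris[, 3])),
                    paste(pmin(tris[, 3], tris[, 1]), pmax(tris[, 3], tris[, 1]))))
  expect_equal(nrow(cons), length(ekeys))
  expect_setequal(paste(pmin(cons$u, cons$v), pmax(cons$u, cons$v)), ekeys)
  # rest lengths equal current edge lengths
  V <- mf$mesh$vertices
  expect_equal(cons$rest_length,
               sqrt(rowSums((V[cons$u, ] - V[cons$v, ])^2)))
})

test_that("gray-to-mass mapping follows the logarithmic law", {
  expect_identical(mass_from_gray(0L), 0.5)
  expect_equal(mass_from_gray(1L), log(2))
  expect_equal(mass_from_gray(255L), log(256))
  masses <- mass_from_gray(0:255)
  expect_true(all(diff(masses) > 0))
  expect_true(all(masses >= 0.5 & masses <= log(256)))
  expect_error(mass_from_gray(-1), "0..255")

  # lookup goes through uv with lower-left origin
  mask <- mask_map(rbind(c(10L, 20L), c(30L, 40L)))  # row 1 = top
  uv <- rbind(c(0.25, 0.25), c(0.75, 0.25), c(0.25, 0.75), c(0.75, 0.75))
  expect_equal(mask_value(mask, uv), c(30L, 40L, 10L, 20L))
  mesh <- tri_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), matrix(1:3, 1),
                   uv = rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(mass_from_mask(mesh, mask), log(c(31, 41, 11)))
  expect_error(mask_value(mask, rbind(c(1.5, 0))), "\\[0, 1\\]")
})

test_that("the explicit Euler step follows the a, v, P update order", {
  cfg <- sim_config(dt = 0.1, damping = 0,
                    external_force = uniform_force(c(0, 0, -4)))
  ps <- particle_system(rbind(c(0, 0, 0)), masses = 2)
  no_springs <- data.frame(u = integer(0), v = integer(0),
                           rest_length = numeric(0))
  out <- euler_step(ps, no_springs, cfg, t = 0)
  expect_equal(out$accelerations[1, ], c(0, 0, -2))
  expect_equal(out$velocities[1, ], c(0, 0, -0.2))
  expect_equal(out$positions[1, ], c(0, 0, -0.02))

  # fixed particle ignores any force
  psf <- particle_system(rbind(c(1, 2, 3)), masses = 2, fixed = TRUE)
  outf <- euler_step(psf, no_springs, cfg, t = 0)
  expect_identical(outf$positions, psf$positions)
  expect_true(all(outf$velocities == 0))

  # zero force, zero velocity is a fixed point
  cfg0 <- sim_config(external_force = uniform_force(c(0, 0, 0)))
  sq <- unit_square_mesh()
  ps0 <- particle_system(sq$vertices, masses = rep(1, 4))
  out0 <- euler_step(ps0, build_constraints(sq), cfg0, t = 0)
  expect_identical(out0$positions, ps0$positions)
})

test_that("velocity constraints cap the predicted spring stretch", {
  mkps <- function(v2) {
    ps <- particle_system(rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(1, 1))
    ps$velocities[2, ] <- v2
    ps
  }
  cons <- data.frame(u = 1L, v = 2L, rest_length = 1)
  cfg <- sim_config(dt = 0.1, tau_c = 0.1)

  # at rest with small relative velocity: nothing is touched
  ps <- mkps(c(0.1, 0, 0))  # predicted length 1.01 < 1.1
  out <- constrain_velocities(ps, cons, cfg)
  expect_identical(out$velocities, ps$velocities)

  # tentative stretch to 1.25 is cut back to exactly 1.1
  ps <- mkps(c(2.5, 0, 0))
  out <- constrain_velocities(ps, cons, cfg)
  pred <- (out$positions[2, ] + cfg$dt * out$velocities[2, ]) -
    (out$positions[1, ] + cfg$dt * out$velocities[1, ])
  expect_lte(sqrt(sum(pred^2)), 1.1 + 1e-12)
  expect_equal(sqrt(sum(pred^2)), 1.1, tolerance = 1e-12)
  # correction split symmetrically between two free endpoints: the sum of
  # the axial velocities (relative momentum proxy) is preserved
  expect_equal(out$velocities[1, 1] + out$velocities[2, 1], 2.5,
               tolerance = 1e-12)

  # inextensible limit tau_c = 0
  cfg0 <- sim_config(dt = 0.1, tau_c = 0)
  out0 <- constrain_velocities(mkps(c(2.5, 0, 0)), cons, cfg0)
  pred0 <- (out0$positions[2, ] + cfg0$dt * out0$velocities[2, ]) -
    (out0$positions[1, ] + cfg0$dt * out0$velocities[1, ])
  expect_lte(sqrt(sum(pred0^2)), 1 + 1e-12)

  # a fixed endpoint absorbs no correction
  psf <- particle_system(rbind(c(0, 0, 0), c(1, 0, 0)), masses = c(1, 1),
                         fixed = c(TRUE, FALSE))
  psf$velocities[2, ] <- c(2.5, 0, 0)
  outf <- constrain_velocities(psf, cons, cfg)
  expect_true(all(outf$velocities[1, ] == 0))
  predf <- (outf$positions[2, ] + cfg$dt * outf$velocities[2, ]) - outf$positions[1, ]
  expect_equal(sqrt(sum(predf^2)), 1.1, tolerance = 1e-12)
})

test_that("kinetic energy decays geometrically under pure damping", {
  set.seed(1)
  cfg <- sim_config(dt = 0.01, damping = 0.5,
                    external_force = uniform_force(c(0, 0, 0)))
  ps <- particle_system(matrix(stats::rnorm(30, sd = 0.1), 10, 3),
                        masses = seq(0.5, 5, length.out = 10))
  ps$velocities <- matrix(stats::rnorm(30), 10, 3)
  no_springs <- data.frame(u = integer(0), v = integer(0),
                           rest_length = numeric(0))
  ke <- kinetic_energy(ps)
  for (i in 1:50) {
    ps <- euler_step(ps, no_springs, cfg, t = i * cfg$dt)
    ke_new <- kinetic_energy(ps)
    expect_lt(ke_new, ke)
    ke <- ke_new
  }
})

test_that("deformation snapshots honour anchors, bounds and determinism", {
  mf <- maple_fixture_mesh()
  mask <- make_mask("dark-edge", mf$keypoints)

  # n_steps = 0 returns only the undeformed snapshot
  r0 <- simulate_deformation(mf$mesh, mask, sim_config(), n_steps = 0)
  expect_length(r0$snapshots, 1)
  expect_equal(attr(r0$snapshots[[1]], "step"), 0L)
  expect_identical(unclass(r0$snapshots[[1]])[, 1:2], unname(mf$mesh$vertices))

  r <- simulate_deformation(mf$mesh, mask, sim_config(), n_steps = 60,
                            snapshot_every = 30)
  # elongation bound holds over the run
  expect_lte(r$max_elongation, 0.1 + 1e-9)
  # anchored vertices are bit-identical across the whole trajectory
  for (s in r$snapshots) {
    expect_identical(s[r$fixed, ], r$snapshots[[1]][r$fixed, ])
  }
  # free vertices actually moved
  expect_gt(max(abs(r$particles$positions[, 3])), 0.01)

  # identical inputs give bit-identical trajectories
  r2 <- simulate_deformation(mf$mesh, mask, sim_config(), n_steps = 60,
                             snapshot_every = 30)
  expect_identical(r$particles$positions, r2$particles$positions)

  # kinetic energy ends below its peak once the external force switches off
  cfg_off <- sim_config(external_force = uniform_force(c(0, 0, -1),
                                                       until = 0.25))
  roff <- simulate_deformation(mf$mesh, mask, cfg_off, n_steps = 200,
                               snapshot_every = 200)
  ke <- roff$log$kinetic_energy
  expect_lt(ke[length(ke)], max(ke))
})

test_that("symmetric mesh, mask and force deform symmetrically", {
  mesh <- symmetric_strip_mesh(4)
  mask <- mask_map(matrix(128L, 8, 8))
  cfg <- sim_config(external_force = uniform_force(c(0, 0, -0.5)))
  r <- simulate_deformation(mesh, mask, cfg, n_steps = 100,
                            snapshot_every = 100,
                            petiole = c(0, 0), anchor_radius = 0.1)
  expect_lt(r$max_elongation, 0.1)  # constraint never engaged
  P <- r$particles$positions
  top <- 6:9
  bot <- 10:13
  expect_lt(max(abs(P[top, 1] - P[bot, 1])), 1e-6)
  expect_lt(max(abs(P[top, 2] + P[bot, 2])), 1e-6)
  expect_lt(max(abs(P[top, 3] - P[bot, 3])), 1e-6)
  # spine stays on the symmetry plane
  expect_lt(max(abs(P[1:5, 2])), 1e-6)
})
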