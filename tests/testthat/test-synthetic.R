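test_that("synthetic outlines satisfy the key-point invariants", {
  # ellipse points lie exactly on the ellipse (no jitter by default)
  el <- make_outline("ellipse", a = 2, b = 1, n_keypoints = 32)
  expect_lt(max(abs((el$points[, 1] / 2)^2 + el$points[, 2]^2 - 1)), 1e-9)
  # counter-clockwise order
  expect_gt(leafcycle:::polygon_signed_area(el$points), 0)

  # maple silhouette is simple per the independent all-pairs oracle
  mp <- make_outline("maple", lobes = 5, lobe_depth = 0.5, n_keypoints = 32,
                     seed = 7)
  expect_true(oracle_polygon_simple(mp$points))

  # determinism and seed sensitivity
  expect_identical(make_outline("maple", seed = 7)$points,
                   make_outline("maple", seed = 7)$points)
  expect_false(identical(make_outline("maple", seed = 7)$points,
                         make_outline("maple", seed = 8)$points))

  # property: random recipes always produce valid key-point sets
  for (k in 1:25) {
    u <- leafcycle:::hash_uniform(321, k, 1:4)
    kp <- make_outline("maple", a = 1 + 2 * u[1], b = 0.5 + u[2],
                       n_keypoints = 16 + round(32 * u[3]),
                       lobes = 3 + (k %% 5), lobe_depth = 0.7 * u[4],
                       seed = k)
    expect_s3_class(kp, "key_point_set")
    expect_true(oracle_polygon_simple(kp$points))
  }

  expect_error(make_outline("maple", n_keypoints = 6), "at least 8")
  expect_error(make_outline("ellipse", lobe_depth = 1), "lobe_depth")
  expect_error(make_outline("ellipse", a = -1), "positive")
})

test_that("synthetic masks paint the requested regions", {
  kp <- make_outline("ellipse", a = 2, b = 1, n_keypoints = 32)

  uni <- make_mask("uniform", kp, value = 128)
  inside_vals <- uni$pixels[uni$pixels != 255L]
  expect_true(length(inside_vals) > 0 && all(inside_vals == 128L))

  de <- make_mask("dark-edge", kp, dark = 16, bright = 200)
  # the centroid pixel is bright, a pixel hugging the boundary is dark
  lookup <- function(mask, xy) {
    bb <- c(range(kp$points[, 1]), range(kp$points[, 2]))
    uv <- cbind((xy[1] - bb[1]) / (bb[2] - bb[1]),
                (xy[2] - bb[3]) / (bb[4] - bb[3]))
    mask_value(mask, uv)
  }
  expect_equal(lookup(de, c(0, 0)), 200L)
  expect_equal(lookup(de, c(1.98, 0)), 16L)
  expect_setequal(unique(as.vector(de$pixels)), c(16L, 200L, 255L))

  bv <- make_mask("bright-vein", kp, dark = 16, bright = 200)
  expect_equal(lookup(bv, c(0, 0)), 200L)      # on the midrib
  expect_equal(lookup(bv, c(0, 0.6)), 16L)     # off the vein corridor
  expect_error(make_mask("uniform", kp, dark = 200, bright = 16), "below")
})

test_that("default senescence specs are valid feed-forward chains", {
  sp <- make_default_spec(2, seed = 1)
  expect_length(sp$states, 2)
  expect_identical(sp$absorbing, c(FALSE, TRUE))

  for (n in c(3, 5, 7)) {
    sp <- make_default_spec(n, seed = n)
    expect_s3_class(sp, "senescence_spec")
    expect_true(all(sp$tau_corners >= 5 & sp$tau_corners <= 60))
    # strictly feed-forward: no backward mass anywhere
    for (k in 1:4) {
      X <- sp$X_corners[, , k]
      expect_true(all(X[lower.tri(X, diag = TRUE)] == 0))
    }
    # every transient state prefers its immediate successor
    for (i in seq_len(n - 2)) {
      expect_gt(mean(sp$X_corners[i, i + 1, ]), mean(sp$X_corners[i, i + 2, ]))
    }
  }
  expect_identical(make_default_spec(4, seed = 2)$X_corners,
                   make_default_spec(4, seed = 2)$X_corners)
  expect_error(make_default_spec(1), "at least 2")
})

test_that("the sliver fan is a valid mesh full of narrow triangles", {
  sf <- sliver_fan_mesh(n_slivers = 20, aspect = 20)
  expect_s3_class(sf, "tri_mesh")
  expect_equal(sum(!sf$boundary), 20L)
  expect_lt(mesh_quality(sf)$min_angle, 5)
  expect_lt(abs(mesh_area(sf) - 1), 1e-9)
})
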