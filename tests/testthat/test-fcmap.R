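test_that("neighbour codes map to offsets per the lexicographic table", {
  expect_equal(as.integer(code_to_offset(0)), c(-1, -1, -1))
  expect_equal(as.integer(code_to_offset(13)), c(0, 0, 0))
  expect_equal(as.integer(code_to_offset(26)), c(1, 1, 1))
  expect_equal(offset_to_code(c(0, 0, 0)), 13L)
  expect_equal(offset_to_code(c(1, 0, 0)), 22L)
  # all 27 codes give 27 distinct offsets covering {-1,0,1}^3
  offs <- code_to_offset(0:26)
  expect_equal(nrow(unique(offs)), 27L)
  expect_true(all(offs %in% -1:1))
  # round trip both ways
  expect_equal(offset_to_code(offs), 0:26)
  grid <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  expect_equal(code_to_offset(offset_to_code(grid)),
               matrix(as.integer(grid), ncol = 3,
                      dimnames = list(NULL, c("dx", "dy", "dz"))))
  expect_error(code_to_offset(27), "range")
  expect_error(offset_to_code(c(2, 0, 0)), "-1, 0, 1")
})

test_that("activation window is strict on both bounds", {
  hu <- array(c(100, 0, 200, -850, 199.999, 0.001, 250, -1000, 50),
              dim = c(3, 3, 1))
  hu <- array(rep(hu, 3), dim = c(3, 3, 3))
  m <- activation_mask(ct_volume(hu))
  expect_true(m[1, 1, 1])       # 100
  expect_false(m[2, 1, 1])      # 0 exactly
  expect_false(m[3, 1, 1])      # 200 exactly
  expect_false(m[1, 2, 1])      # -850 parenchyma
  expect_true(m[2, 2, 1])       # just below 200
  expect_error(activation_mask(ct_volume(hu), c(200, 0)), "below")
})

test_that("affinity is the min endpoint objectness, symmetric and monotone", {
  expect_equal(affinity(100, 100), 0.5)
  expect_equal(affinity(100, 100, c(0, 200)), affinity(100, 100))
  set.seed(2)
  a <- stats::runif(20, 1, 199); b <- stats::runif(20, 1, 199)
  expect_equal(affinity(a, b), affinity(b, a))
  expect_equal(affinity(a, b), pmin(a, b) / 200)
  # monotone limit toward the upper bound
  expect_gt(affinity(199.99, 199.99), 0.999)
  expect_error(affinity(250, 100), "active")
})

test_that("a straight active line propagates codes toward the seed", {
  hu <- array(-1000, dim = c(3, 3, 3))
  hu[1:3, 2, 2] <- 100
  fc <- compute_fc(ct_volume(hu), c(0, 1, 1))
  expect_equal(fc$codes[1:3, 2, 2], c(13L, 4L, 4L))  # 4 = (-1, 0, 0)
  expect_equal(fc$strength[1:3, 2, 2], c(1, 0.5, 0.5))
  # deactivated voxels keep code 13, strength 0
  expect_true(all(fc$codes[hu == -1000] == 13L))
  expect_true(all(fc$strength[hu == -1000] == 0))
})

test_that("voxels outside the window always get code 13 and strength 0", {
  set.seed(3)
  hu <- random_hu_grid(c(5, 5, 5))
  hu[3, 3, 3] <- 100
  hu[1, 1, 1] <- 250
  fc <- compute_fc(ct_volume(hu), c(2, 2, 2))
  inactive <- !(hu > 0 & hu < 200)
  expect_true(all(fc$codes[inactive] == 13L))
  expect_true(all(fc$strength[inactive] == 0))
})

test_that("strength equals the brute-force max-min path closure", {
  set.seed(4)
  for (i in 1:12) {
    hu <- random_hu_grid(c(4, 4, 4), p_inactive = 0.3)
    seed <- c(1, 1, 1)
    hu[2, 2, 2] <- stats::runif(1, 50, 150)  # ensure an active seed
    fc <- compute_fc(ct_volume(hu), seed)
    oracle <- fw_maxmin_strength(hu, seed)
    expect_lt(max(abs(fc$strength - oracle)), 1e-12)
  }
})

test_that("the predecessor walk is monotone, acyclic, and ends at the seed", {
  b <- small_phantom(11)
  fc <- compute_fc(b$ct, b$seed)
  reached <- which(fc$strength > 0, arr.ind = TRUE) - 1L
  set.seed(5)
  sel <- reached[sample(nrow(reached), min(400, nrow(reached))), ,
                 drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    v <- sel[i, ]
    nxt <- strongest_neighbor_step(fc, v)
    expect_gte(fc$strength[nxt[1] + 1, nxt[2] + 1, nxt[3] + 1],
               fc$strength[v[1] + 1, v[2] + 1, v[3] + 1])
  }
  ends <- t(apply(sel[1:50, , drop = FALSE], 1L,
                  function(v) walk_to_fixed_point(fc, v)))
  expect_true(all(ends[, 1] == b$seed[1] & ends[, 2] == b$seed[2] &
                    ends[, 3] == b$seed[3]))
})

test_that("strongest_neighbor_step follows the stored code", {
  hu <- array(100, dim = c(8, 8, 8))
  fc <- compute_fc(ct_volume(hu), c(4, 4, 4))
  expect_equal(strongest_neighbor_step(fc, c(4, 4, 4)), c(4, 4, 4))  # seed
  fc$codes[6, 6, 6] <- 22L   # (1, 0, 0)
  expect_equal(strongest_neighbor_step(fc, c(5, 5, 5)), c(6, 5, 5))
})

test_that("seed handling: snapping, bounds, and deactivated seeds", {
  hu <- array(-1000, dim = c(5, 5, 5))
  hu[3, 3, 3] <- 100
  ct <- ct_volume(hu)
  expect_error(compute_fc(ct, c(9, 0, 0)), "outside")
  # seed on inactive voxel snaps to the active one two voxels away
  fc <- compute_fc(ct, c(0, 2, 2), snap_radius = 5)
  expect_equal(fc$seed, c(2L, 2L, 2L))
  expect_error(compute_fc(ct, c(0, 0, 0), snap_radius = 1), "snap radius")
  expect_error(compute_fc(ct, c(0, 0, 0), snap_radius = 0), "deactivated")
})

test_that("repeated runs are bit-identical", {
  set.seed(6)
  hu <- random_hu_grid(c(6, 6, 6))
  hu[3, 3, 3] <- 120
  a <- compute_fc(ct_volume(hu), c(2, 2, 2))
  b <- compute_fc(ct_volume(hu), c(2, 2, 2))
  expect_identical(a$codes, b$codes)
  expect_identical(a$strength, b$strength)
})
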