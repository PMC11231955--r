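cube_mask <- function(dims, from, to) {
  m <- array(FALSE, dim = dims)
  m[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- TRUE
  m
}

test_that("dice follows the overlap formula and its conventions", {
  d <- c(6, 6, 6)
  a <- cube_mask(d, c(1, 1, 1), c(2, 2, 1))    # 4 voxels
  b <- cube_mask(d, c(1, 1, 1), c(2, 2, 2))    # 8 voxels, contains a
  expect_equal(dice(a, b), 8 / 12)
  expect_equal(dice(a, a), 1)
  expect_equal(dice(a, b), dice(b, a))
  disjoint <- cube_mask(d, c(5, 5, 5), c(6, 6, 6))
  expect_equal(dice(a, disjoint), 0)
  empty <- array(FALSE, dim = d)
  expect_equal(dice(empty, empty), 1)          # documented convention
  expect_equal(dice(a, empty), 0)
  expect_error(dice(a, array(FALSE, dim = c(3, 3, 3))), "dims")
})

test_that("surface voxels are the 6-connectivity boundary", {
  d <- c(5, 5, 5)
  cube <- cube_mask(d, c(2, 2, 2), c(4, 4, 4))   # 3x3x3 solid
  s <- surface_voxels(cube)
  expect_equal(sum(s), 26)                        # all but the centre
  expect_false(s[3, 3, 3])
  single <- cube_mask(d, c(3, 3, 3), c(3, 3, 3))
  expect_equal(surface_voxels(single), single)
  expect_equal(sum(surface_voxels(array(FALSE, dim = d))), 0)
  # border of the grid counts as outside: a full grid is all surface... no -
  # interior voxels away from the border are not surface
  full <- array(TRUE, dim = d)
  sf <- surface_voxels(full)
  expect_true(sf[1, 1, 1])
  expect_false(sf[3, 3, 3])
})

test_that("parallel plates give the closed-form ASD", {
  d <- c(9, 7, 7)
  a <- cube_mask(d, c(3, 2, 2), c(3, 6, 6))   # single-voxel-thick 5x5 plate
  b <- cube_mask(d, c(6, 2, 2), c(6, 6, 6))   # 3 voxels away along x
  expect_equal(asd(a, b), 3.0)
  expect_equal(asd(b, a), asd(a, b))          # symmetric definition
  # same separation along z with z-spacing 2 mm doubles the distance
  dz <- c(7, 7, 9)
  az <- cube_mask(dz, c(2, 2, 3), c(6, 6, 3))
  bz <- cube_mask(dz, c(2, 2, 6), c(6, 6, 6))
  expect_equal(asd(az, bz, spacing = c(1, 1, 2)), 6.0)
  expect_equal(asd(a, a), 0)
  expect_error(asd(a, array(FALSE, dim = d)), "empty")
})

test_that("asd matches the all-pairs brute force on random masks", {
  set.seed(20)
  for (i in 1:8) {
    d <- c(8, 8, 8)
    a <- array(stats::runif(prod(d)) < 0.3, dim = d)
    b <- array(stats::runif(prod(d)) < 0.3, dim = d)
    if (sum(a) == 0 || sum(b) == 0) next
    sp <- sample(c(1, 1.5, 2), 3, replace = TRUE)
    expect_equal(asd(a, b, sp), brute_asd(a, b, sp), tolerance = 1e-9)
  }
})

test_that("both metrics are invariant to a common translation", {
  d <- c(10, 10, 10)
  a <- cube_mask(d, c(2, 2, 2), c(4, 5, 4))
  b <- cube_mask(d, c(3, 2, 2), c(5, 5, 4))
  shift <- function(m) {
    out <- array(FALSE, dim = d)
    out[4:10, 3:10, 3:10] <- m[1:7, 1:8, 1:8]
    out
  }
  expect_equal(dice(shift(a), shift(b)), dice(a, b))
  expect_equal(asd(shift(a), shift(b)), asd(a, b))
})

test_that("per-lobe report covers all lobes with correct global means", {
  d <- c(12, 8, 8)
  lab <- array(0L, dim = d)
  lab[1:2, 2:6, 2:6] <- 1L
  lab[3:4, 2:6, 2:6] <- 2L
  lab[5:6, 2:6, 2:6] <- 3L
  lab[7:8, 2:6, 2:6] <- 4L
  lab[9:10, 2:6, 2:6] <- 5L
  gt <- lobe_label_map(lab)
  rep0 <- per_lobe_report(gt, gt)
  expect_equal(rep0$per_lobe$dice, rep(1, 5))
  expect_equal(rep0$per_lobe$asd_mm, rep(0, 5))
  expect_equal(rep0$global_dice, 1)

  # shift one lobe by one voxel: its ASD is about one voxel spacing
  lab2 <- lab
  lab2[lab == 5L] <- 0L
  lab2[10:11, 2:6, 2:6] <- 5L
  pred <- lobe_label_map(lab2)
  rep1 <- per_lobe_report(pred, gt)
  rl <- rep1$per_lobe[rep1$per_lobe$lobe == "RL", ]
  expect_lt(abs(rl$asd_mm - 1), 0.6)
  expect_lt(rl$dice, 1)
  others <- rep1$per_lobe[rep1$per_lobe$lobe != "RL", ]
  expect_equal(others$dice, rep(1, 4))
  expect_equal(rep1$global_dice, mean(rep1$per_lobe$dice))
  expect_equal(rep1$global_asd, mean(rep1$per_lobe$asd_mm))

  # a lobe absent from both maps is skipped with a note
  lab3 <- lab; lab3[lab == 4L] <- 0L
  both <- lobe_label_map(lab3)
  rep2 <- per_lobe_report(both, both)
  rm_row <- rep2$per_lobe[rep2$per_lobe$lobe == "RM", ]
  expect_equal(rm_row$note, "empty in both")
  expect_true(is.na(rm_row$dice))
  expect_equal(rep2$global_dice, 1)   # mean over the four present lobes
})

test_that("paired t-test matches the closed form and flags edge cases", {
  set.seed(21)
  x <- stats::rnorm(20, 0.9, 0.1)
  y <- x - 0.5 + stats::rnorm(20, 0, 0.05)
  res <- paired_ttest(x, y)
  d <- x - y
  expect_equal(res$t, mean(d) / (stats::sd(d) / sqrt(20)), tolerance = 1e-10)
  expect_equal(res$p, 2 * stats::pt(abs(res$t), 19, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(res$p, 0.01)
  expect_equal(res$mean_diff, mean(d))
  expect_error(paired_ttest(x, x), "variance")
  expect_error(paired_ttest(x[1:2], y[1:2]), "3 pairs")
  expect_error(paired_ttest(x, y[1:10]), "equal length")
})

test_that("fissures appear only at lobe-lobe interfaces", {
  d <- c(8, 6, 6)
  lab <- array(0L, dim = d)
  lab[2:4, 2:5, 2:5] <- 1L   # LU slab
  lab[5:7, 2:5, 2:5] <- 2L   # LL slab abutting it at x = 4|5
  lobes <- lobe_label_map(lab)
  fis <- fissure_from_lobes(lobes)
  # two one-voxel-thick sheets at the interface
  expect_true(all(which(fis, arr.ind = TRUE)[, 1] %in% c(4, 5)))
  expect_equal(sum(fis), 2 * 4 * 4)
  # single lobe -> no fissure; background contact does not count
  lab_single <- array(0L, dim = d)
  lab_single[2:4, 2:5, 2:5] <- 1L
  expect_equal(sum(fissure_from_lobes(lobe_label_map(lab_single))), 0)
  # non-paired lobes touching (LU|RU) produce nothing
  lab_np <- lab; lab_np[lab == 2L] <- 3L
  lab_np[lab == 2L] <- 3L
  fis_np <- fissure_from_lobes(lobe_label_map(lab_np))
  expect_equal(sum(fis_np), 0)
})
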