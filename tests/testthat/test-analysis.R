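test_that("PDD extraction normalizes and orients depth correctly", {
  arr <- array(1, dim = c(9, 9, 12))
  d <- synthetic_dose(arr, voxel = c(1, 1, 0.5))
  pdd <- extract_pdd(d)
  expect_true(all(pdd$value == 100))
  expect_equal(pdd$coordinate, seq(0.25, 5.75, by = 0.5))
  # normalization idempotent
  pdd2 <- extract_pdd(synthetic_dose(array(pdd$value,
                                           dim = c(1, 1, 12))[rep(1, 3),
                                                              rep(1, 3), ,
                                                              drop = FALSE],
                                     voxel = c(1, 1, 0.5)))
  expect_equal(pdd2$value, pdd$value)
  # depth is measured from the top surface: put dose near the top only
  arr2 <- array(0, dim = c(9, 9, 12))
  arr2[, , 11] <- 1   # second voxel from the top
  p2 <- extract_pdd(synthetic_dose(arr2, voxel = c(1, 1, 0.5)))
  expect_equal(p2$coordinate[which.max(p2$value)], 0.75)
  expect_error(extract_pdd(d, axis_position = c(50, 0)), "outside")
})

test_that("profiles pick out the requested line", {
  arr <- array(0, dim = c(11, 11, 10))
  arr[6, 4, 5] <- 1  # delta dose at one voxel
  d <- synthetic_dose(arr, voxel = c(1, 1, 1))
  ztop <- d$grid$origin[3] + 10
  depth <- ztop - (d$grid$origin[3] + (5 - 0.5)) # voxel 5 centre depth
  pr <- extract_profile(d, depth = depth, along = "y",
                        at = d$grid$origin[1] + 5.5, normalize = "none",
                        window = 0.5)
  expect_equal(sum(pr$value > 0), 1)
  expect_equal(which(pr$value > 0), 4)
  # symmetric dose -> symmetric profile; "half" display convention
  arr3 <- array(rep(dnorm(seq(-2, 2, length.out = 11)), each = 11),
                dim = c(11, 11, 1))
  d3 <- synthetic_dose(aperm(array(arr3, c(11, 11, 1)), c(2, 1, 3)))
  pr3 <- extract_profile(d3, depth = 0.5, along = "y", normalize = "half",
                         window = 0.5)
  expect_equal(max(pr3$value), 50)
  expect_equal(pr3$value, rev(pr3$value))
})

test_that("mean relative difference behaves like a pointwise error", {
  a <- structure(data.frame(coordinate = 1:50, value = 100 * exp(-(1:50) / 30)),
                 class = c("dose_curve", "data.frame"))
  expect_equal(mean_relative_difference(a, a), 0)
  b <- a; b$value <- 1.05 * a$value
  expect_equal(mean_relative_difference(a, b), 5, tolerance = 1e-9)
  # invariant to a common rescaling
  a2 <- a; a2$value <- a$value * 3
  b2 <- b; b2$value <- b$value * 3
  expect_equal(mean_relative_difference(a2, b2),
               mean_relative_difference(a, b))
  cdisj <- a; cdisj$coordinate <- a$coordinate + 100
  expect_error(mean_relative_difference(a, cdisj), "disjoint")
})

test_that("gamma index matches the brute-force oracle point for point", {
  set.seed(41)
  # smooth random reference plane, 24 x 24 at 2 mm
  base <- outer(sin(seq(0, 3, length.out = 24)),
                cos(seq(0, 2, length.out = 24))) + 2
  ref <- 50 * base
  ev <- ref * (1 + 0.04 * matrix(runif(576, -1, 1), 24))
  g <- gamma_index(ref, ev, dta = 3, dd = 3, spacing = 2)
  gb <- gamma_brute(ref, ev, dta = 3, dd = 3, spacing = 2,
                    spacing_eval = 2 / 3) # oracle on the refined plane
  # pass/fail agreement via the package's own refinement: recompute the
  # oracle on the same interpolated evaluated plane the package searches
  evf <- tbimc:::.refine_plane(ev, c(2, 2), 1)$m
  gb2 <- gamma_brute(ref, evf, dta = 3, dd = 3, spacing = 2,
                     spacing_eval = 1)
  expect_equal(g$gamma_map[g$gamma_map <= 1], gb2[g$gamma_map <= 1],
               tolerance = 1e-9)
  expect_identical(g$gamma_map <= 1, gb2 <= 1)
})

test_that("gamma criteria respond to shifts and offsets as geometry says", {
  ref <- matrix(rep(seq(20, 100, length.out = 40), 20), nrow = 40)
  # identical planes: all pass at 100%
  g0 <- gamma_index(ref, ref, dta = 3, dd = 3, spacing = 1)
  expect_equal(g0$pass_rate, 100)
  expect_true(all(g0$gamma_map[g0$mask] <= 1e-9))
  # in-plane shift by dta/2: distance term <= 0.5 everywhere
  ev <- ref[c(2:40, 40), ] # shift by one 1 mm pixel against dta = 2 mm
  g1 <- gamma_index(ref, ev, dta = 2, dd = 3, spacing = 1)
  expect_equal(g1$pass_rate, 100)
  # uniform offset of 2 x dd with no shift: fails except where the
  # gradient rescues points within dta
  ev2 <- ref + 2 * 3 / 100 * max(ref)
  g2 <- gamma_index(ref, ev2, dta = 3, dd = 3, spacing = 1)
  grad_rescue <- 3 * diff(ref[1:2, 1]) # dose change over one dta
  if (grad_rescue < 3 / 100 * max(ref)) {
    expect_lt(g2$pass_rate, 5)
  }
  expect_warning(gamma_index(ref, ref, dta = 0.5, dd = 3, spacing = 1),
                 "coarser")
})

test_that("the efficiency metric follows its definition", {
  fake <- function(sd_noise) {
    i <- 0
    function(run) {
      i <<- i + 1
      arr <- array(1 + sd_noise * sin(run * 17), dim = c(4, 4, 4))
      synthetic_dose(arr, voxel = c(1, 1, 1))
    }
  }
  res <- estimate_efficiency(fake(0.1), n_runs = 5,
                             box_center = c(0, 0, 8), box_size = 2)
  expect_false(res$degenerate)
  expect_equal(res$efficiency, 1 / (res$variance * res$time))
  expect_length(res$doses, 5)
  expect_warning(
    resd <- estimate_efficiency(fake(0), n_runs = 3,
                                box_center = c(0, 0, 8), box_size = 2),
    "degenerate")
  expect_true(is.infinite(resd$efficiency))
  expect_error(estimate_efficiency(fake(0.1), n_runs = 1,
                                   box_center = c(0, 0, 8)))
})

test_that("curve tools are consistent between index and world coordinates", {
  # the same physical dose in two voxelizations gives the same curve values
  arr <- array(rep(exp(-(1:30) / 10), each = 25), dim = c(5, 5, 30))
  d1 <- synthetic_dose(arr, voxel = c(2, 2, 0.5))
  p1 <- extract_pdd(d1, lateral_window = 3)
  arrp <- arr[, , rep(1:30, each = 2)]
  d2 <- synthetic_dose(arrp, voxel = c(2, 2, 0.25))
  p2 <- extract_pdd(d2, lateral_window = 3)
  v2 <- approx(p2$coordinate, p2$value, xout = p1$coordinate)$y
  expect_equal(p1$value, v2, tolerance = 1e-6)
})
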