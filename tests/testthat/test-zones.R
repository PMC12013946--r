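make_disc <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`)
  d2 <= r^2
}

test_that("mid-slice selection picks the in-focus middle plane", {
  arr <- array(10, c(9, 20, 20))
  nuc <- array(TRUE, dim(arr))
  arr[5, 5:10, 5:10] <- 100                   # structure only in plane 5
  stk <- voxel_stack(arr)
  expect_equal(select_mid_slice(stk, nuc), 5)
  # identical planes: tie broken toward lowest z of the middle third
  flat <- voxel_stack(array(10, c(9, 20, 20)))
  expect_equal(select_mid_slice(flat, nuc), 4)
  thin <- array(FALSE, c(9, 20, 20)); thin[4:5, , ] <- TRUE
  expect_error(select_mid_slice(stk, thin), "fewer than 3 planes")
})

test_that("mid-slice of a synthetic territory sits at the blob center", {
  sim <- quiet_sim(seed = 7)
  nuc <- segment_nucleus(subtract_background(sim$dapi))
  z <- select_mid_slice(sim$signal, nuc)
  expect_lte(abs(z - sim$truth$mid_slice), 1)
})

test_that("moment ellipse fit recovers discs and elongated ellipses", {
  disc <- make_disc(121, 50)
  e <- fit_ellipse(disc)
  expect_lt(abs(e$a - 50) / 50, 0.01)
  expect_lt(abs(e$b - 50) / 50, 0.01)

  n <- 161
  yy <- matrix(seq_len(n), n, n); xx <- t(yy)
  ell <- ((xx - 81) / 60)^2 + ((yy - 81) / 30)^2 <= 1
  f <- fit_ellipse(ell)
  expect_lt(abs(f$a / f$b - 2) / 2, 0.02)
  rot <- t(ell)                                # 90 degree rotation
  g <- fit_ellipse(rot)
  expect_equal(g$a, f$a, tolerance = 1e-9)     # axes swap roles, sizes persist
  expect_equal(g$b, f$b, tolerance = 1e-9)
  expect_equal(sum(rot), sum(ell))
  expect_error(fit_ellipse(ell & FALSE), "empty mask")
  line <- matrix(FALSE, 20, 20); line[10, 3:18] <- TRUE
  expect_error(fit_ellipse(line), "collinear")
})

test_that("ellipticity gate passes ellipses and rejects crosses", {
  disc <- make_disc(101, 40)
  e <- fit_ellipse(disc)
  qc <- check_ellipticity(disc, e)
  expect_gte(qc$score, 0.98)
  expect_true(qc$pass)

  plus <- matrix(FALSE, 101, 101)
  plus[41:61, 11:91] <- TRUE; plus[11:91, 41:61] <- TRUE
  pe <- fit_ellipse(plus)
  pq <- check_ellipticity(plus, pe)
  expect_false(pq$pass)
  expect_true(check_ellipticity(plus, pe, min_overlap = 0)$pass)
})

test_that("the three zones are equal-area within discretization", {
  # target: pixel counts pairwise within 2% for semi-axes >= 20 px
  shapes <- list(c(a = 90, b = 90), c(a = 60, b = 30), c(a = 45, b = 22),
                 c(a = 20, b = 20))
  for (s in shapes) {
    n <- 2 * ceiling(s[["a"]]) + 21
    yy <- matrix(seq_len(n), n, n); xx <- t(yy)
    c0 <- (n + 1) / 2
    mask <- ((xx - c0) / s[["a"]])^2 + ((yy - c0) / s[["b"]])^2 <= 1
    zones <- make_zones(fit_ellipse(mask), dim(mask))
    areas <- c(sum(zones$central), sum(zones$intermediate), sum(zones$peripheral))
    expect_lt((max(areas) - min(areas)) / min(areas), 0.02)
    if (s[["a"]] == 90)                       # analytic check for the disc
      expect_lt(max(abs(areas - pi * 90^2 / 3)) / (pi * 90^2 / 3), 0.02)
  }
})

test_that("zone partition is disjoint and confined to the fitted ellipse", {
  disc <- make_disc(151, 60)
  zones <- make_zones(fit_ellipse(disc), dim(disc))
  overlap <- (zones$central & zones$intermediate) |
    (zones$central & zones$peripheral) |
    (zones$intermediate & zones$peripheral)
  expect_false(any(overlap))
  tiny <- structure(list(center = c(cy = 5, cx = 5), a = 0.8, b = 0.6,
                         theta = 0), class = "Ellipse2D")
  expect_error(make_zones(tiny, c(10, 10)), "too small")
  big <- structure(list(center = c(cy = 5, cx = 5), a = 30, b = 20,
                        theta = 0), class = "Ellipse2D")
  expect_warning(make_zones(big, c(10, 10)), "clipped")
})

test_that("zone fractions sum to one and localize as expected", {
  disc <- make_disc(151, 60)
  zones <- make_zones(fit_ellipse(disc), dim(disc))
  uni <- zone_fractions(disc, zones)          # uniform signal over the disc
  expect_equal(sum(uni), 1, tolerance = 1e-9)
  expect_true(all(abs(uni - 1 / 3) < 0.02))
  inner <- make_disc(151, 10)                 # entirely inside the central zone
  expect_equal(unname(zone_fractions(inner, zones)), c(1, 0, 0))
  expect_error(zone_fractions(disc & FALSE, zones), "no signal")
})

test_that("central territories load the central zone", {
  sim <- quiet_sim(seed = 5, f_true = 0.1, r_true = 0)
  z <- sim$truth$mid_slice
  zones <- make_zones(fit_ellipse(sim$truth$nucleus_mask[z, , ]),
                      dim(sim$truth$nucleus_mask[z, , ]))
  p <- zone_fractions(sim$truth$territory_mask[z, , ], zones)
  expect_gte(p[["p_central"]], p[["p_periph"]])
})

test_that("intensity-weighted zone fractions are available", {
  disc <- make_disc(151, 60)
  zones <- make_zones(fit_ellipse(disc), dim(disc))
  w <- matrix(1, 151, 151)
  w[zones$central] <- 10                       # weight concentrates centrally
  pw <- zone_fractions(disc, zones, weights = w)
  pu <- zone_fractions(disc, zones)
  expect_gt(pw[["p_central"]], pu[["p_central"]])
  expect_equal(sum(pw), 1, tolerance = 1e-9)
})
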