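hexagon_ring <- function(radius = 1.39, tilt = NULL) {
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- cbind(radius * cos(ang), radius * sin(ang), 0)
  names <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  atoms <- tibble::tibble(resid = "PHE", elety = c(names, "CB"),
                          x = c(ring[, 1], 2.2), y = c(ring[, 2], 1.2),
                          z = c(ring[, 3], 0.4))
  atoms
}

test_that("aromatic frames sit at the ring centroid, normal to the plane", {
  fr <- residue_frame(hexagon_ring())
  expect_equal(fr$origin, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(abs(fr$z), c(0, 0, 1), tolerance = 1e-9)
  expect_lt(abs(sum(fr$x * fr$y)), 1e-9)
  expect_equal(packnet:::cross3(fr$x, fr$y), fr$z, tolerance = 1e-9)
})

test_that("branched frames use the fork plane and fail on collinear forks", {
  val <- tibble::tibble(resid = "VAL", elety = c("CB", "CG1", "CG2"),
                        x = c(0, 1.3, -0.6), y = c(0, 0.6, 1.2),
                        z = c(0, 0, 0))
  fr <- residue_frame(val)
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(abs(fr$z), c(0, 0, 1), tolerance = 1e-9)
  collinear <- tibble::tibble(resid = "VAL",
                              elety = c("CB", "CG1", "CG2"),
                              x = c(0, 1, 2), y = 0, z = 0)
  expect_error(residue_frame(collinear), "collinear")
  missing <- tibble::tibble(resid = "LEU", elety = c("CG", "CD1"),
                            x = c(0, 1), y = c(0, 1), z = 0)
  expect_error(residue_frame(missing), "missing")
})

test_that("frames from built residues are orthonormal and right-handed", {
  for (res in c("ALA", "VAL", "LEU", "ILE", "PHE", "TYR")) {
    fr <- residue_frame(build_peptide(res))
    expect_lt(abs(sum(fr$x * fr$y)), 1e-9)
    expect_lt(abs(sum(fr$x * fr$z)), 1e-9)
    expect_equal(packnet:::vnorm(fr$x), 1, tolerance = 1e-9)
    expect_equal(packnet:::cross3(fr$x, fr$y), fr$z, tolerance = 1e-9)
  }
})

test_that("triangle geometry recovers closed-form sides and angles", {
  fr <- gen_triplet_frames(c(5.5, 5.5, 5.5))
  tg <- triangle_geometry(fr, "none")
  expect_equal(unname(tg$r), c(5.5, 5.5, 5.5), tolerance = 1e-9)
  expect_equal(unname(tg$omega), c(60, 60, 60), tolerance = 1e-9)

  tg2 <- triangle_geometry(gen_triplet_frames(c(3, 4, 5)), "none")
  expect_equal(unname(tg2$omega), c(90, 53.13, 36.87), tolerance = 1e-3)
  expect_equal(sum(tg2$omega), 180, tolerance = 1e-9)
  expect_equal(packnet:::cross3(tg2$z_tr, tg2$x_tr), tg2$y_tr,
               tolerance = 1e-12)
})

test_that("tilt and swivel report the prescribed angles", {
  fr <- gen_triplet_frames(c(5, 5, 5), tilts = c(90, 45, 170),
                           swivels = c(0, 90, 312))
  tg <- triangle_geometry(fr, "none")
  expect_equal(unname(tilt_angles(tg)), c(90, 45, 170), tolerance = 1e-9)
  expect_equal(unname(swivel_angles(tg)), c(0, 90, 312), tolerance = 1e-6)
})

test_that("swivel is flagged undefined at zero tilt projection", {
  f <- new_residue_frame(c(0, 0, 0), x = c(1, 0, 0), z = c(0, 0, 1))
  tri <- list(z_tr = c(0, 0, 1),
              frames = list(f, f, f))
  class(tri) <- "triangle_geometry"
  expect_warning(ph <- swivel_angles(tri), "undefined")
  expect_true(all(is.na(ph)))
})

test_that("round trip of sides, tilt and swivel is exact to 1e-6", {
  set.seed(31)
  for (i in 1:40) {
    sides <- stats::runif(3, 4, 7) # any triple in [4,7] satisfies the
    tilts <- stats::runif(3, 5, 175) # triangle inequality
    swivels <- stats::runif(3, 0, 359.9)
    fr <- gen_triplet_frames(sides, tilts, swivels)
    tg <- triangle_geometry(fr, "none")
    expect_equal(unname(tg$r), sides, tolerance = 1e-6)
    expect_equal(unname(tilt_angles(tg)), tilts, tolerance = 1e-6)
    expect_equal(unname(swivel_angles(tg)), swivels, tolerance = 1e-6)
  }
})

test_that("tilt and swivel are invariant under rigid-body motion", {
  rot <- packnet:::rotation_matrix(c(1, 2, 3), 73)
  shift <- c(4, -2, 9)
  fr <- gen_triplet_frames(c(5, 5.5, 6), tilts = c(70, 100, 40),
                           swivels = c(10, 200, 330))
  moved <- lapply(fr, function(f) {
    new_residue_frame(as.numeric(rot %*% f$origin) + shift,
                      x = as.numeric(rot %*% f$x),
                      z = as.numeric(rot %*% f$z))
  })
  t1 <- tilt_angles(triangle_geometry(fr, "none"))
  t2 <- tilt_angles(triangle_geometry(moved, "none"))
  expect_equal(t1, t2, tolerance = 1e-9)
  s1 <- swivel_angles(triangle_geometry(fr, "none"))
  s2 <- swivel_angles(triangle_geometry(moved, "none"))
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("triplet frames reject invalid side lengths", {
  expect_error(gen_triplet_frames(c(1, 1, 5)), "triangle inequality")
})

test_that("composition classes order residues by volume conventions", {
  c1 <- composition_class(c("LEU", "PHE", "VAL"))
  expect_equal(c1$class, "C1")
  expect_equal(c1$residues, c("PHE", "LEU", "VAL")) # descending volume
  c2 <- composition_class(c("ALA", "ALA", "LEU"))
  expect_equal(c2$class, "C2")
  expect_equal(c2$residues[1], "LEU") # the unique residue is R1
  c3 <- composition_class(c("LEU", "LEU", "LEU"))
  expect_equal(c3$class, "C3")
  expect_error(composition_class(c("LEU", "XXX", "VAL")), "unknown")
})

test_that("C2 templates make the first tilt acute; C3 choice is stable", {
  set.seed(17)
  mk_frames <- function(resids) {
    sides <- c(5.2, 5.6, 5.9)
    tilts <- stats::runif(3, 20, 160)
    swivels <- stats::runif(3, 0, 359)
    gen_triplet_frames(sides, tilts, swivels, residues = resids)
  }
  fr <- mk_frames(c("LEU", "PHE", "PHE"))
  tg <- triangle_geometry(fr, "C2")
  expect_equal(tg$frames[[1]]$residue, "LEU")
  expect_lte(tilt_angles(tg)[1], 90 + 1e-9)

  # C3: a family of same-composition triplets (noisy copies of one base
  # geometry with scrambled labels) gives near-identical superposed angle
  # statistics regardless of the starting template
  base <- gen_triplet_frames(c(5.2, 5.6, 5.9), tilts = c(70, 100, 40),
                             swivels = c(15, 200, 330),
                             residues = rep("LEU", 3))
  trip <- purrr::map(1:12, function(i) {
    rot <- packnet:::rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 360))
    shift <- stats::rnorm(3, 0, 5)
    perm <- sample(3)
    purrr::map(base[perm], function(f) {
      new_residue_frame(
        as.numeric(rot %*% (f$origin + stats::rnorm(3, 0, 0.05))) + shift,
        x = as.numeric(rot %*% f$x), z = as.numeric(rot %*% f$z),
        residue = "LEU")
    })
  })
  mean_tilt <- function(template_idx) {
    template <- triangle_geometry(trip[[template_idx]], "C3")
    angles <- vapply(trip[-template_idx], function(f) {
      mean(tilt_angles(triangle_geometry(f, "C3", template = template)))
    }, numeric(1))
    mean(angles)
  }
  expect_lt(abs(mean_tilt(1) - mean_tilt(2)), 1)
})

test_that("analytic random tilt fractions integrate correctly", {
  f6 <- random_tilt_fractions("6bin-30")
  expect_equal(round(100 * f6$fraction, 1),
               c(6.7, 18.3, 25.0, 25.0, 18.3, 6.7))
  expect_equal(sum(f6$fraction), 1, tolerance = 1e-12)
  f3 <- random_tilt_fractions("3bin-30-folded")
  expect_equal(round(100 * f3$fraction, 1), c(13.4, 36.6, 50.0))
  expect_equal(f3$fraction, 2 * f6$fraction[1:3], tolerance = 1e-12)
  expect_equal(sum(f3$fraction), 1, tolerance = 1e-12)
})

test_that("chi-squared test matches expectations and critical values", {
  # counts exactly proportional to the null give statistic 0
  f6 <- random_tilt_fractions("6bin-30")
  centres <- (f6$bin_lo + f6$bin_hi) / 2
  obs <- rep(centres, round(6000 * f6$fraction))
  res <- chi2_angles(obs, "tilt-random-6bin")
  expect_lt(res$statistic, 1.2) # rounding of bin counts only
  expect_equal(res$df, 5)
  expect_equal(res$critical, stats::qchisq(0.95, 5))

  res3 <- chi2_angles(stats::runif(200, 0, 180), "tilt-random-3bin")
  expect_equal(res3$df, 2)
  expect_error(chi2_angles(numeric(0)), "empty")
  expect_true(chi2_angles(rep(15, 100), "swivel-uniform")$significant)
})

test_that("isotropic samples converge to the sine null", {
  x <- gen_tilt_sample(1e5, "isotropic", seed = 3)
  res <- chi2_angles(x, "tilt-random-6bin")
  frac <- res$table$observed / res$n
  expect_true(all(abs(frac - res$table$fraction) < 0.005))
  expect_false(res$significant)
})

test_that("composition combinatorics give 35, 42, 7 for seven residues", {
  cc <- composition_combinations(7)
  expect_equal(cc$combinations, c(35, 42, 7))
  expect_length(hydrophobic_residues(), 7)
})

test_that("sequence separation splits local and non-local at 10", {
  out <- sequence_separation(c(15, 22, 26))
  expect_equal(out$locality[out$res_i == 15 & out$res_j == 22], "local")
  expect_equal(out$locality[out$res_i == 15 & out$res_j == 26], "non-local")
  expect_equal(out$locality[out$res_i == 22 & out$res_j == 26], "local")
  out2 <- sequence_separation(c(15, 25, 150))
  expect_equal(out2$locality, c("local", "non-local", "non-local"))
  expect_error(sequence_separation(c(1, 5, 9), chain = c("A", "A", "B")),
               "different chains")
})
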