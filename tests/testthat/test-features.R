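cfg_small <- feature_config(hog_radial_sigmas = c(2, 4), entropy_window = 3,
                            haralick_window = 5, haralick_levels = 4)

test_that("Fourier HOG maps vanish for constant images and commute with
           90-degree rotation", {
  cfg <- feature_config()
  maps <- fourier_hog(matrix(3.7, 24, 24), cfg)
  for (nm in names(maps)) {
    expect_true(all(abs(maps[[nm]]) < 1e-12), info = nm)
  }

  set.seed(13)
  x <- matrix(runif(29 * 29), 29, 29)
  m0 <- fourier_hog(x, cfg_small)
  m90 <- fourier_hog(rot90(x), cfg_small)
  for (nm in names(m0)) {
    expect_lt(max(abs(m90[[nm]] - rot90(m0[[nm]]))), 1e-6)
  }
})

test_that("Fourier HOG on a linear ramp matches the angular-moment
           integration oracle at the center", {
  n <- 33
  ramp <- matrix(rep(0:(n - 1), each = n), n, n)  # I(r,c) = c
  cfg <- feature_config(hog_max_order = 4, hog_radial_sigmas = c(2, 4))
  maps <- fourier_hog(ramp, cfg)
  # the ramp's gradient is (1, 0) everywhere: angle 0, magnitude 1. The
  # angular moment of every order m is exp(i*m*0) = 1 and its convolution
  # with a unit-mass radial profile integrates to 1.
  for (m in 0:4) {
    for (sg in c(2, 4)) {
      oracle <- sum(outer(gaussian_kernel_oracle(sg),
                          gaussian_kernel_oracle(sg)) * 1)
      got <- maps[[sprintf("fhog_m%d_s%g", m, sg)]][17, 17]
      expect_equal(got, oracle, tolerance = 1e-3,
                   info = sprintf("m=%d sigma=%g", m, sg))
    }
  }
})

test_that("Haralick maps reproduce degenerate and enumerated GLCM cases", {
  # constant image: single-symbol GLCM
  h <- haralick_maps(matrix(5, 10, 10), cfg_small)
  expect_equal(h$haralick_energy, matrix(1, 10, 10))
  expect_equal(h$haralick_entropy, matrix(0, 10, 10))
  expect_equal(h$haralick_contrast, matrix(0, 10, 10))

  # two-level checkerboard, single offset (0,1): contrast exactly 1
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  cfg_cb <- feature_config(haralick_window = 15, haralick_levels = 2,
                           haralick_offsets = matrix(c(0L, 1L), 1))
  hcb <- haralick_maps(cb, cfg_cb)
  g <- glcm_enumerate(matrix(as.integer(cb > 0), 4, 4), 2, 0, 1)
  st <- glcm_stats_direct(g)
  expect_equal(st$contrast, 1)
  expect_equal(hcb$haralick_contrast[2, 2], st$contrast)
  expect_equal(hcb$haralick_energy[3, 1], st$energy)
  expect_equal(hcb$haralick_correlation[1, 4], st$correlation)
})

test_that("Haralick maps agree with the pair-enumeration oracle on random
           grids including borders", {
  set.seed(31)
  offs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (rep in 1:5) {
    x <- matrix(runif(9 * 9), 9, 9)
    cfg <- feature_config(haralick_window = 5, haralick_levels = 4,
                          haralick_offsets = offs)
    got <- haralick_maps(x, cfg)
    q <- floor((x - min(x)) / (max(x) - min(x)) * 4)
    q[q >= 4] <- 3
    for (px in list(c(1, 1), c(5, 5), c(9, 3), c(2, 8))) {
      r <- px[1]; c <- px[2]
      r0 <- max(1, r - 2); r1 <- min(9, r + 2)
      c0 <- max(1, c - 2); c1 <- min(9, c + 2)
      qwin <- q[r0:r1, c0:c1]
      gs <- lapply(seq_len(nrow(offs)), function(o) {
        glcm_enumerate(qwin, 4, offs[o, 1], offs[o, 2])
      })
      p <- Reduce(`+`, gs) / length(gs)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_equal(p, t(p), tolerance = 1e-12)
      st <- glcm_stats_direct(p)
      for (nm in names(st)) {
        expect_equal(got[[paste0("haralick_", nm)]][r, c], st[[nm]],
                     tolerance = 1e-10,
                     info = sprintf("%s at (%d,%d)", nm, r, c))
      }
    }
  }
})

test_that("local entropy matches direct histogram computation", {
  expect_equal(local_entropy(matrix(2, 8, 8), cfg_small), matrix(0, 8, 8))

  # 2x2 image, window covers it all: two bins with half the mass each
  x2 <- matrix(c(0, 0, 1, 1), 2, 2)
  expect_equal(local_entropy(x2, cfg_small), matrix(1, 2, 2))

  set.seed(5)
  x <- matrix(runif(12 * 12), 12, 12)
  cfg <- feature_config(entropy_window = 9, entropy_bins = 32)
  got <- local_entropy(x, cfg)
  for (r in c(1, 5, 12)) {
    for (c in c(1, 7, 12)) {
      win <- x[max(1, r - 4):min(12, r + 4), max(1, c - 4):min(12, c + 4)]
      expect_equal(got[r, c], entropy_direct(win, 32, min(x), max(x)),
                   tolerance = 1e-9)
    }
  }
})

test_that("ridge orientation matches brute-force steering and the membrane
           detector prefers lines over blobs", {
  n <- 41
  line <- matrix(0, n, n)
  line[21, ] <- 1
  cfg <- feature_config()
  rf <- ridge_filter(line, cfg)
  phi <- rf$orientation[21, 21]
  # along-ridge direction of a horizontal line is 0 (mod pi)
  expect_lt(min(abs(phi), abs(phi - pi)), 2 * pi / 180)
  oracle <- steer_orientation(rf$rxx[21, 21], rf$rxy[21, 21],
                              rf$ryy[21, 21])
  expect_lt(min(abs(phi - oracle), abs(abs(phi - oracle) - pi)),
            2 * pi / 180)

  blob <- matrix(0, n, n)
  d2 <- outer((1:n - 21)^2, (1:n - 21)^2, "+")
  blob <- exp(-d2 / (2 * 2^2))  # isotropic Gaussian blob, peak 1
  sal_line <- cmd_map(line, cfg)
  sal_blob <- cmd_map(blob, cfg)
  expect_gt(sal_line[21, 21], sal_blob[21, 21])
})

test_that("membrane-detector saliency is equivariant under 90-degree
           rotation", {
  n <- 41
  line <- matrix(0, n, n)
  line[21, 8:34] <- 1
  cfg <- feature_config()
  sal <- cmd_map(line, cfg)
  sal_rot <- cmd_map(rot90(line), cfg)
  expect_lt(max(abs(sal_rot - rot90(sal))), 1e-6)
  rf <- ridge_filter(line, cfg)
  rf_rot <- ridge_filter(rot90(line), cfg)
  # along-ridge direction rotates by 90 degrees (angles compared mod pi)
  d <- abs(rf_rot$orientation[21, 21] -
           (rf$orientation[21, 21] + pi / 2)) %% pi
  expect_lt(min(d, pi - d), 1e-6)
})

test_that("extracellular component size map assigns component areas", {
  # tissue everywhere: no extracellular space
  st <- corrected_stack(matrix(1, 12, 12), structural = matrix(1, 12, 12))
  expect_equal(ecs_map(st), matrix(0, 12, 12))

  # frame enclosing one rectangular hole
  s <- matrix(1, 15, 15)
  s[5:9, 4:11] <- 0  # hole of area 40
  sth <- corrected_stack(s, structural = s)
  e <- ecs_map(sth)
  expect_true(all(e[5:9, 4:11] == 40))
  expect_true(all(e[s == 1] == 0))

  # random masks vs flood-fill oracle
  set.seed(9)
  for (i in 1:5) {
    m <- matrix(runif(20 * 20) > 0.5, 20, 20)
    stm <- corrected_stack(matrix(1, 20, 20),
                           structural = matrix(as.numeric(m), 20, 20))
    em <- ecs_map(stm)
    lab <- flood_fill_label(!m, 8)
    areas <- tabulate(lab[lab > 0])
    exp_map <- matrix(0, 20, 20)
    exp_map[lab > 0] <- areas[lab[lab > 0]]
    expect_equal(em, exp_map)
  }
})

test_that("per-nucleus summaries compute the four statistics per region", {
  h <- 20; w <- 20
  px <- as.matrix(expand.grid(row = 8:11, col = 8:11))
  nuc <- make_nucleus(px)
  mk_maps <- function(nuclear_map, structural_map = nuclear_map) {
    structure(list(image_id = "fix", height = h, width = w,
                   maps = list(nuclear = list(f = nuclear_map),
                               structural = list(f = structural_map))),
              class = "pixel_feature_maps")
  }
  cfg <- feature_config(ring_radius = 3)

  # constant map
  v <- summarize_nucleus(mk_maps(matrix(2.5, h, w)), nuc, cfg)
  expect_equal(unname(v["nuclear.f.nucleus.mean"]), 2.5)
  expect_equal(unname(v["nuclear.f.ring.median"]), 2.5)
  expect_equal(unname(v["structural.f.nucleus.std"]), 0)
  expect_equal(unname(v["structural.f.ring.mad"]), 0)

  # known values {1,2,3,4,100} on a 5-pixel nucleus
  px5 <- cbind(row = rep(5L, 5), col = 3:7)
  nuc5 <- make_nucleus(px5)
  m5 <- matrix(0, h, w)
  m5[cbind(px5[, 1] + 1, px5[, 2] + 1)] <- c(1, 2, 3, 4, 100)
  v5 <- summarize_nucleus(mk_maps(m5), nuc5, cfg)
  expect_equal(unname(v5["nuclear.f.nucleus.mean"]), 22)
  expect_equal(unname(v5["nuclear.f.nucleus.median"]), 3)
  expect_equal(unname(v5["nuclear.f.nucleus.mad"]), 1)
  expect_equal(unname(v5["nuclear.f.nucleus.std"]), sd(c(1, 2, 3, 4, 100)))

  # disjoint regions: 5 on the nucleus, 7 everywhere else
  md <- matrix(7, h, w)
  md[cbind(px[, 1] + 1, px[, 2] + 1)] <- 5
  vd <- summarize_nucleus(mk_maps(md), nuc, cfg)
  expect_equal(unname(vd["nuclear.f.nucleus.mean"]), 5)
  expect_equal(unname(vd["nuclear.f.ring.mean"]), 7)

  # nucleus covering the whole image: empty ring, zeros with warning
  pxall <- as.matrix(expand.grid(row = 0:(h - 1), col = 0:(w - 1)))
  expect_warning(vall <- summarize_nucleus(mk_maps(matrix(1, h, w)),
                                           make_nucleus(pxall), cfg),
                 "empty ring")
  expect_equal(unname(vall["nuclear.f.ring.mean"]), 0)
})

test_that("the default descriptor has a stable name set of plausible size", {
  sp <- scene_spec(height = 160, width = 160, n_target_nuclei = 2,
                   n_other_nuclei = 4, min_center_separation = 24, seed = 3)
  sc <- generate_scene(sp)
  res <- process_image(sc$stack)
  fcols <- setdiff(names(res$features), c("nucleus_id", "image_id"))
  expect_gte(length(fcols), 100)
  expect_lte(length(fcols), 1000)
  # naming is a pure function of the config: a second run is identical
  res2 <- process_image(sc$stack)
  expect_identical(names(res$features), names(res2$features))
  expect_equal(res$features, res2$features)
})

test_that("per-image standardization yields zero mean, unit variance", {
  set.seed(77)
  f <- data.frame(nucleus_id = rep(1:6, 2),
                  image_id = rep(c("a", "b"), each = 6),
                  x1 = rnorm(12, 5, 2), x2 = rnorm(12, -3, 0.5),
                  const = 1)
  s <- scale_per_image(f)
  for (img in c("a", "b")) {
    sel <- s$image_id == img
    expect_equal(mean(s$x1[sel]), 0, tolerance = 1e-9)
    expect_equal(sd(s$x1[sel]), 1, tolerance = 1e-9)
    expect_equal(mean(s$x2[sel]), 0, tolerance = 1e-9)
    expect_true(all(s$const[sel] == 0))
  }
  # pooled mean is generally nonzero even though per-image means are zero
  pooled_raw <- abs(mean(f$x1[f$image_id == "a"]) -
                    mean(f$x1[f$image_id == "b"]))
  expect_gt(pooled_raw, 0)

  f1 <- f[1, ]
  expect_warning(s1 <- scale_per_image(f1), "fewer than 2")
  expect_true(all(s1[, c("x1", "x2", "const")] == 0))
})
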