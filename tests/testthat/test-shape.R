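test_that("normalize_shape hits the target area and centres the centroid", {
  set.seed(10)
  # identity: centred disc already at target area
  d <- raster_disc(64, 15)
  dn <- normalize_shape(d, target_area = sum(d))
  expect_gte(mean(d == dn), 0.995)   # unchanged up to resampling tolerance
  expect_equal(sum(dn), sum(d))

  # 4x the area shrinks to target +/- 1 px
  big <- raster_disc(128, 40)
  out <- normalize_shape(big, target_area = round(sum(big) / 4))
  expect_lte(abs(sum(out) - round(sum(big) / 4)), 1)

  # translated shape gets recentred
  off <- raster_disc(96, 12, cy = 20, cx = 70)
  cen <- colMeans(which(normalize_shape(off, sum(off)) > 0, arr.ind = TRUE))
  expect_lt(max(abs(cen - (96 + 1) / 2)), 0.5 + 1e-9)

  expect_error(normalize_shape(matrix(0L, 8, 8), 10), "empty")
})

test_that("area conservation holds on random fixtures", {
  set.seed(42)
  for (i in 1:100) {
    b <- random_blob(48)
    tgt <- round(sum(b) * runif(1, 0.5, 1.5))
    out <- normalize_shape(b, target_area = tgt)
    expect_lte(abs(sum(out) - tgt), 1)
  }
})

test_that("differential distance transform: signs, values, disc radius", {
  # single centre pixel
  one <- matrix(0L, 9, 9); one[5, 5] <- 1L
  dd <- differential_distance_transform(one)
  expect_true(dd[5, 5] > 0)
  expect_equal(sum(dd > 0), 1)

  # disc of radius R: DDT at centroid = R up to discretisation
  disc <- raster_disc(101, 30)
  expect_lt(abs(differential_distance_transform(disc)[51, 51] - 30), 1.01)

  # value equality against the brute-force nearest-neighbour oracle
  set.seed(7)
  for (i in 1:10) {
    m <- random_binary(16)
    if (sum(m) == 0 || sum(m) == 256) next
    expect_equal(differential_distance_transform(m), brute_ddt(m),
                 tolerance = 1e-10)
  }
  expect_error(differential_distance_transform(matrix(2, 3, 3)), "binary")
})

test_that("chimera synthesis: idempotence, radial blend, errors", {
  tp <- shape_templates(size = 128, target_area = 3000)
  t1 <- tp$oval; storage.mode(t1) <- "integer"
  expect_identical(synthesize_chimera(list(tp$oval)), t1)
  expect_identical(synthesize_chimera(rep(list(tp$oval), 7)), t1)

  # two concentric discs: chimera radius at the zero-crossing of summed DDTs
  s <- 101
  small <- raster_disc(s, 15); large <- raster_disc(s, 35)
  chim <- synthesize_chimera(list(small, large))
  # 1-D radial oracle: sum of signed distances (r-15)+(r-35) crosses 0 at 25
  r_emp <- sqrt(sum(chim) / pi)
  expect_lt(abs(r_emp - 25), 1.5)

  expect_error(synthesize_chimera(list()), "at least one")
  expect_error(synthesize_chimera(list(small, matrix(0L, 5, 5))), "grid")
})

test_that("moment descriptors: circle, 2:1 ellipse, convex solidity", {
  circ <- raster_disc(201, 70)
  expect_lt(eccentricity(circ), 0.05)
  expect_lt(abs(length_width(circ) - 1), 0.02)
  expect_gt(solidity(circ), 0.98)
  expect_lte(solidity(circ), 1)

  ell <- raster_ellipse(241, a = 100, b = 50)
  expect_equal(length_width(ell), 2, tolerance = 0.02)
  expect_equal(eccentricity(ell), sqrt(3) / 2, tolerance = 0.01)

  sq <- matrix(0L, 64, 64); sq[10:50, 10:50] <- 1L
  expect_gt(solidity(sq), 0.99)
})

test_that("degenerate shapes are flagged", {
  line <- matrix(0L, 21, 21); line[11, 3:19] <- 1L
  expect_warning(e <- eccentricity(line), "degenerate")
  expect_equal(e, 1)
  expect_error(length_width(line), "degenerate")
})

test_that("unsigned Manhattan chain code counts axis moves", {
  rect <- matrix(0L, 40, 60); rect[11:25, 6:45] <- 1L  # h=15 rows, w=40 cols
  u <- umcc(rect)
  expect_equal(unname(u["UKUX"]), log10(2 * 40))  # horizontal moves = 2w
  expect_equal(unname(u["UKUY"]), log10(2 * 15))  # vertical moves = 2h

  sqr <- matrix(0L, 32, 32); sqr[8:24, 8:24] <- 1L
  us <- umcc(sqr)
  expect_equal(us[["UKUX"]], us[["UKUY"]])

  # 10^UKUX + 10^UKUY equals the total boundary move count on random blobs
  set.seed(3)
  for (i in 1:20) {
    b <- random_blob(32)
    ub <- umcc(b)
    total <- sum(b[-nrow(b), ] != b[-1, ]) + sum(b[1, ]) + sum(b[nrow(b), ]) +
      sum(b[, -ncol(b)] != b[, -1]) + sum(b[, 1]) + sum(b[, ncol(b)])
    expect_equal(10^ub[["UKUX"]] + 10^ub[["UKUY"]], total, tolerance = 1e-9)
  }
  expect_error(umcc(matrix(0L, 5, 5)), "contour")
})

test_that("slope-chain tortuosity: convex baseline, waviness monotone", {
  mk_blob <- function(amp, k = 8, size = 256, R = 60) {
    cx <- (size + 1) / 2
    y <- matrix(seq_len(size), size, size); x <- t(y)
    th <- atan2(y - cx, x - cx); r <- sqrt((x - cx)^2 + (y - cx)^2)
    m <- matrix(0L, size, size)
    m[r <= R + amp * sin(k * th)] <- 1L
    m
  }
  circ <- mk_blob(0)
  sq <- matrix(0L, 128, 128); sq[30:90, 30:90] <- 1L

  # total turning is one full turn for both circle and square
  expect_equal(abs(total_turning(circ)), 1, tolerance = 1e-6)
  expect_equal(abs(total_turning(sq)), 1, tolerance = 1e-6)
  # convex contours are near the 2-turn floor; the square's turning is
  # concentrated at 4 corners but sums the same
  expect_equal(tortuosity(sq), 2, tolerance = 0.05)

  # waviness strictly increases tortuosity; starburst beats circle
  t_amp <- vapply(c(0, 4, 8, 12), function(a) tortuosity(mk_blob(a)), 1)
  expect_true(all(diff(t_amp) > 0))
  expect_gt(tortuosity(mk_blob(12)), tortuosity(circ))
})

test_that("descriptors are invariant to pre-normalisation translation", {
  base <- raster_ellipse(201, a = 60, b = 40)
  shifted <- matrix(0L, 201, 201)
  shifted[31:201, 1:171] <- base[1:171, 31:201]
  a <- shape_descriptors(normalize_shape(base, 8000))
  b <- shape_descriptors(normalize_shape(shifted, 8000))
  expect_equal(unlist(a), unlist(b), tolerance = 0.02)
})

test_that("chimera descriptor table covers each genotype-year", {
  tp <- shape_templates(size = 128, target_area = 3000)
  sc <- simulate_shape_scores(4, 5, class_bias = c(.4, .3, .1, .1, .1),
                              years = c("2011", "2012"), seed = 9)
  d <- chimera_descriptors(sc, tp)
  expect_equal(nrow(d), 8)
  expect_true(all(c("UKEC", "UKLvW", "UKTO", "UKSO", "UKUX", "UKUY") %in%
                    names(d)))
  expect_true(all(d$UKSO <= 1 & d$UKSO > 0))
  expect_true(all(d$UKEC >= 0 & d$UKEC < 1))
  bad <- sc; bad$shape_class[1] <- "cube"
  expect_error(chimera_descriptors(bad, tp), "unknown shape")
})
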