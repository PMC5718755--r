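box10 <- list(origin = c(0, 0, 0), dims = c(10, 10, 10))

test_that("cell density is presence fraction over cell volume", {
  traj <- make_hydration_trajectory(c(7, 7, 7), matrix(c(3, 3, 3), 1, 3),
                                    presence_prob = 1, n_frames = 10)
  g <- water_density_map(traj, box = box10)
  expect_equal(g$values[3, 3, 3], 1 / 0.7^3, tolerance = 1e-12)
  expect_equal(g$values[3, 3, 3], 2.9155, tolerance = 1e-4)
  expect_equal(sum(g$values > 0), 1)

  # deterministic 50% presence via an explicit two-state schedule
  traj2 <- make_hydration_trajectory(c(7, 7, 7), matrix(c(3, 3, 3), 1, 3),
                                     presence_prob = 0.5, n_frames = 4000,
                                     seed = 2)
  g2 <- water_density_map(traj2, box = box10)
  expect_equal(g2$values[3, 3, 3] * 0.7^3, 0.5, tolerance = 0.05)
})

test_that("stochastic hotspot density lands within the binomial band", {
  p <- 0.8; nf <- 2000
  traj <- make_hydration_trajectory(c(7, 7, 7), matrix(c(5, 5, 5), 1, 3),
                                    presence_prob = p, n_frames = nf,
                                    seed = 4)
  g <- water_density_map(traj, box = box10)
  tol <- 3 * sqrt(p * (1 - p) / nf) / 0.7^3
  expect_lt(abs(g$values[5, 5, 5] - p / 0.7^3), tol)
  # values are bounded by 1/spacing^3
  expect_lte(max(g$values), 1 / 0.7^3 + 1e-12)
})

test_that("box defaults to the padded reference bounding box", {
  traj <- make_hydration_trajectory(c(7, 7, 7), matrix(c(3, 3, 3), 1, 3),
                                    presence_prob = 1, n_frames = 5)
  g <- water_density_map(traj, ref_selection = 1:2, padding = 2,
                         spacing = 0.7, align = FALSE)
  expect_equal(g$origin, c(-2, -2, -2))
  expect_equal(g$dims, as.integer(ceiling((c(7, 7, 7) + 4) / 0.7)))
  expect_error(water_density_map(trajectory(atom_table(n = 2),
                                            matrix(0, 2, 3))),
               "no water oxygens")
})

test_that("blob segmentation matches a flood-fill oracle", {
  g <- structure(list(origin = c(0, 0, 0), spacing = 0.7,
                      dims = c(6L, 6L, 6L), values = array(0, c(6, 6, 6)),
                      n_frames = 1L), class = "density_grid")
  expect_equal(nrow(threshold_blobs(g, k = 3)), 0)

  # two separated single-cell hotspots
  g$values[1, 1, 1] <- 1; g$values[5, 5, 5] <- 1
  b2 <- threshold_blobs(g, k = 3)
  expect_equal(nrow(b2), 2)
  expect_equal(b2$volume, rep(0.7^3, 2), tolerance = 1e-12)

  # contiguous 3x3x3 block is a single 27-cell blob
  g$values[] <- 0
  g$values[2:4, 2:4, 2:4] <- 1
  b3 <- threshold_blobs(g, k = 3)
  expect_equal(nrow(b3), 1)
  expect_equal(b3$n_cells, 27)

  # oracle: independent recursive flood fill over the mask
  mask <- g$values > 3 * 0.0333
  lab <- array(0L, dim(mask)); nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  cur <- 0L
  for (i in which(mask)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    stack <- i
    while (length(stack)) {
      s <- stack[1]; stack <- stack[-1]
      if (lab[s] > 0) next
      lab[s] <- cur
      sc <- arrayInd(s, dim(mask))
      for (r in seq_len(nrow(nb))) {
        cc <- sc + nb[r, ]
        if (any(cc < 1) || any(cc > dim(mask))) next
        j <- cc[1] + 6 * (cc[2] - 1) + 36 * (cc[3] - 1)
        if (mask[j] && lab[j] == 0) stack <- c(stack, j)
      }
    }
  }
  expect_equal(max(lab), nrow(b3))
})

test_that("MRC round trip is lossless at float32", {
  set.seed(83)
  g <- structure(list(origin = c(-1.5, 2.25, 0), spacing = 0.7,
                      dims = c(4L, 5L, 6L),
                      values = array(runif(120), c(4, 5, 6)),
                      n_frames = 10L), class = "density_grid")
  f <- withr::local_tempfile(fileext = ".mrc")
  write_mrc(g, f)
  back <- read_mrc(f)
  expect_equal(back$dims, g$dims)
  expect_equal(back$spacing, g$spacing, tolerance = 1e-6)
  expect_equal(back$origin, g$origin, tolerance = 1e-6)
  # float32 keeps ~7 significant digits
  expect_equal(back$values, g$values, tolerance = 1e-6)

  # all-zero grid still writes a valid file
  g$values[] <- 0
  write_mrc(g, f)
  expect_equal(max(abs(read_mrc(f)$values)), 0)
})

test_that("an isolated sphere has its exact analytic area", {
  s <- sasa(matrix(0, 1, 3), radii = 1.6)
  expect_equal(s$total, 4 * pi * 3^2, tolerance = 1e-9)
  far <- sasa(rbind(c(0, 0, 0), c(100, 0, 0)), radii = c(1.6, 1.5))
  expect_equal(far$per_atom, 4 * pi * c(3^2, 2.9^2), tolerance = 1e-9)
})

test_that("fused spheres match the spherical-cap closed form within 1%", {
  r1 <- 1.7; r2 <- 1.5; probe <- 1.4; d <- 2.0
  s <- sasa(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(r1, r2), probe = probe)
  exp1 <- cap_accessible_area(r1 + probe, r2 + probe, d)
  exp2 <- cap_accessible_area(r2 + probe, r1 + probe, d)
  expect_lt(abs(s$per_atom[1] - exp1) / exp1, 0.01)
  expect_lt(abs(s$per_atom[2] - exp2) / exp2, 0.01)
})

test_that("total SASA is invariant under rigid motion", {
  set.seed(89)
  coords <- matrix(rnorm(15, sd = 2), 5, 3)
  radii <- runif(5, 1.2, 1.9)
  base <- sasa(coords, radii)$total
  tot <- vapply(1:20, function(i)
    sasa(apply_transform(coords, random_transform()), radii)$total,
    numeric(1))
  expect_lt(max(abs(tot - base)) / base, 0.005)
})

test_that("buried area is symmetric and vanishes at large separation", {
  at <- atom_table(n = 4, elety = "CA", resno = 1:4)
  mk <- function(sep) {
    co <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(sep, 0, 0), c(sep + 1.5, 0, 0))
    trajectory(at, array(co, c(4, 3, 1)))
  }
  far <- buried_area_trace(mk(100), 1:2, 3:4, window_ns = 0.24)
  expect_equal(far$buried, 0, tolerance = 1e-9)
  ab <- buried_area_trace(mk(4), 1:2, 3:4, window_ns = 0.24)
  ba <- buried_area_trace(mk(4), 3:4, 1:2, window_ns = 0.24)
  expect_equal(ab$buried, ba$buried, tolerance = 1e-12)
  expect_error(buried_area_trace(mk(4), 1:2, 2:3), "overlap")

  # monotonic decay to zero on the two-sphere fixture
  at2 <- atom_table(n = 2, elety = "CA", resno = 1:2)
  bur <- vapply(c(2, 3, 4, 5, 6.2), function(d) {
    tr <- trajectory(at2, array(rbind(c(0, 0, 0), c(d, 0, 0)), c(2, 3, 1)))
    buried_area_trace(tr, 1, 2, window_ns = 0.24)$buried
  }, numeric(1))
  expect_true(all(diff(bur) < 1e-9))
  expect_equal(bur[5], 0, tolerance = 1e-9)

  # two-sphere buried area vs the closed form within 1%
  r <- at2$vdw[1]; probe <- 1.4; d <- 3.0
  tr <- trajectory(at2, array(rbind(c(0, 0, 0), c(d, 0, 0)), c(2, 3, 1)))
  got <- buried_area_trace(tr, 1, 2, window_ns = 0.24)$buried
  re <- r + probe
  analytic <- 2 * (4 * pi * re^2 - cap_accessible_area(re, re, d))
  expect_lt(abs(got - analytic) / analytic, 0.01)
})

test_that("two-water bridges are counted per the three-leg geometry", {
  at <- atom_table(n = 4, elety = c("O1G", "OH2", "OH2", "OE1"),
                   element = "O", resno = c(1, 2, 3, 4),
                   is_water_oxygen = c(FALSE, TRUE, TRUE, FALSE))
  co <- rbind(c(0, 0, 0), c(2.8, 0, 0), c(5.4, 0, 0), c(8.0, 0, 0))
  expect_equal(two_water_bridge_count(co, at, 1, 4), 1L)
  # no waters at all
  at0 <- at; at0$is_water_oxygen <- FALSE
  expect_equal(two_water_bridge_count(co, at0, 1, 4), 0L)
  expect_error(two_water_bridge_count(co, at, integer(0), 4), "nonempty")
})

test_that("bridge counting agrees with a brute-force double loop", {
  set.seed(97)
  for (rep in 1:10) {
    nw <- 10
    at <- atom_table(n = nw + 2, elety = c("O1G", rep("OH2", nw), "OE1"),
                     element = "O", resno = seq_len(nw + 2),
                     is_water_oxygen = c(FALSE, rep(TRUE, nw), FALSE))
    co <- rbind(c(0, 0, 0), matrix(runif(3 * nw, 0, 8), nw, 3), c(7, 0, 0))
    got <- two_water_bridge_count(co, at, 1, nw + 2)
    w <- 1 + seq_len(nw)
    cnt <- 0L
    for (i in seq_len(nw - 1)) {
      for (j in seq.int(i + 1, nw)) {
        wi <- co[w[i], ]; wj <- co[w[j], ]
        d_ab <- function(p, s) sqrt(sum((p - co[s, ])^2))
        if (sqrt(sum((wi - wj)^2)) > 3.5) next
        ok <- (d_ab(wi, 1) <= 3.5 && d_ab(wj, nw + 2) <= 3.5) ||
              (d_ab(wj, 1) <= 3.5 && d_ab(wi, nw + 2) <= 3.5)
        if (ok) cnt <- cnt + 1L
      }
    }
    expect_equal(got, cnt)
  }
})
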