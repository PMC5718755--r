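test_that("quadric fit is exact on representable surfaces", {
  grid <- sheet_grid(7, 3)
  flat <- fit_quadric(cbind(grid, 0))
  expect_equal(unname(flat$coefficients), rep(0, 6), tolerance = 1e-12)
  expect_equal(flat$residual_rms, 0, tolerance = 1e-12)

  par <- fit_quadric(cbind(grid, grid[, 1]^2 + grid[, 2]^2))
  expect_equal(par$coefficients[["a2"]], 1, tolerance = 1e-10)
  expect_equal(par$coefficients[["a5"]], 1, tolerance = 1e-10)
  expect_equal(par$coefficients[["a4"]], 0, tolerance = 1e-10)
  expect_equal(par$coefficients[["a0"]], 0, tolerance = 1e-10)
  expect_lt(par$residual_rms, 1e-10)

  expect_error(fit_quadric(cbind(1:10, 2 * (1:10), rnorm(10))),
               "rank-deficient")
  expect_error(fit_quadric(matrix(0, 5, 3)), "at least 6")
})

test_that("noisy saddle fit agrees with hand-built normal equations", {
  set.seed(13)
  grid <- sheet_grid(7, 3)
  z <- 0.3 * grid[, 1]^2 - 0.2 * grid[, 2]^2 + 0.1 * grid[, 1] * grid[, 2] +
    rnorm(nrow(grid), sd = 0.1)
  fit <- fit_quadric(cbind(grid, z))
  X <- cbind(1, grid[, 1], grid[, 1]^2, grid[, 2],
             grid[, 1] * grid[, 2], grid[, 2]^2)
  oracle <- solve(t(X) %*% X, t(X) %*% z)
  expect_equal(unname(fit$coefficients), as.numeric(oracle),
               tolerance = 1e-9)
})

test_that("curvature formulas are applied literally", {
  expect_equal(curvature(c(a0 = 0, a1 = 0, a2 = 1, a3 = 0, a4 = 0, a5 = 1)),
               list(M = 4, G = -4, M_sq = 16))
  expect_equal(curvature(c(a0 = 0, a1 = 0, a2 = 1, a3 = 0, a4 = 0, a5 = -1)),
               list(M = 0, G = 4, M_sq = 0))
  expect_equal(curvature(c(a0 = 0, a1 = 0, a2 = 0, a3 = 0, a4 = 0, a5 = 0)),
               list(M = 0, G = 0, M_sq = 0))
})

test_that("M and G are invariant under x/y relabeling (a2 <-> a5)", {
  set.seed(17)
  for (rep in 1:10) {
    a <- rnorm(6)
    c1 <- curvature(setNames(a, paste0("a", 0:5)))
    swapped <- a[c(1, 4, 6, 2, 5, 3)]  # x<->y: a1<->a3, a2<->a5
    c2 <- curvature(setNames(swapped, paste0("a", 0:5)))
    expect_equal(c1$M, c2$M, tolerance = 1e-12)
    expect_equal(c1$G, c2$G, tolerance = 1e-12)
  }
})

test_that("curvature series is constant on a static trajectory", {
  traj <- make_sheet_trajectory(sheet_grid(7, 3),
                                matrix(rep(c(0, 0, 0.08, 0, 0.02, 0.05), 4),
                                       4, 6, byrow = TRUE))
  cs <- curvature_series(traj)
  expect_equal(cs$M, rep(cs$M[1], 4), tolerance = 1e-10)
  expect_equal(cs$G, rep(cs$G[1], 4), tolerance = 1e-10)
})

test_that("curvature series recovers a coefficient schedule", {
  nf <- 20
  a2 <- seq(0, 0.1, length.out = nf)
  sched <- cbind(0, 0, a2, 0, 0, 0.05)
  grid <- sheet_grid(7, 3)
  traj <- make_sheet_trajectory(grid, sched, noise_sd = 0)
  cs <- curvature_series(traj, reference = cbind(grid, 0),
                         canonicalize = FALSE)
  expect_equal(cs$M, 2 * (a2 + 0.05), tolerance = 1e-4)
})

test_that("curvature series is invariant under global rigid motion", {
  grid <- sheet_grid(7, 3)
  traj <- make_sheet_trajectory(grid,
                                matrix(rep(c(0, 0, 0.06, 0, 0.01, 0.04), 3),
                                       3, 6, byrow = TRUE),
                                noise_sd = 0.05, seed = 9)
  ref <- cbind(grid, 0)
  base <- curvature_series(traj, reference = ref, canonicalize = FALSE)
  set.seed(19)
  tf <- random_transform()
  rot <- traj
  for (k in 1:3) rot$coords[, , k] <- apply_transform(traj$coords[, , k], tf)
  moved <- curvature_series(rot, reference = ref, canonicalize = FALSE)
  expect_equal(moved$M, base$M, tolerance = 1e-8)
  expect_equal(moved$G, base$G, tolerance = 1e-8)
})

test_that("landscape normalization puts the modal bin at zero energy", {
  pmf <- build_pmf(c(rep(0.5, 5)), c(rep(0.5, 5)), seq(0, 1, 0.5),
                   seq(0, 1, 0.5))
  expect_equal(min(pmf$energy[is.finite(pmf$energy)]), 0)
  expect_equal(sum(is.finite(pmf$energy)), 1)
  expect_equal(max(pmf$rho), 1)

  # two bins with counts 1000 and 368
  msq <- c(rep(0.25, 1000), rep(0.75, 368))
  pmf2 <- build_pmf(msq, rep(0.5, 1368), seq(0, 1, 0.5), c(0, 1))
  e <- pmf2$energy[is.finite(pmf2$energy)]
  expect_equal(diff(range(e)), log(1000 / 368), tolerance = 1e-12)
  expect_equal(log(1000 / 368), 0.9997, tolerance = 1e-4)

  # uniform counts -> all occupied energies zero
  pmf3 <- build_pmf(c(0.25, 0.75), c(0.25, 0.75), seq(0, 1, 0.5),
                    seq(0, 1, 0.5))
  expect_equal(max(pmf3$energy[is.finite(pmf3$energy)]), 0)
})

test_that("merging identical landscapes is a no-op with zero shift", {
  set.seed(23)
  pmf <- build_pmf(runif(200), runif(200), seq(0, 1, 0.1), seq(0, 1, 0.1))
  m <- merge_pmfs(pmf, pmf)
  expect_equal(m$delta, 0, tolerance = 1e-12)
  expect_equal(m$energy[m$overlap], pmf$energy[m$overlap], tolerance = 1e-12)
})

test_that("a constant energy offset is recovered exactly as the shift", {
  set.seed(29)
  pmf_a <- build_pmf(runif(300), runif(300), seq(0, 1, 0.1), seq(0, 1, 0.1))
  for (c_ in c(3, -1.5, 0.25)) {
    pmf_b <- pmf_a
    pmf_b$energy <- pmf_a$energy - c_   # E_b = E_a - c  =>  delta = c
    m <- merge_pmfs(pmf_a, pmf_b)
    expect_equal(m$delta, c_, tolerance = 1e-10)
    expect_equal(m$energy[m$overlap], pmf_a$energy[m$overlap],
                 tolerance = 1e-10)
  }
})

test_that("the shift matches a brute-force scan of the weighted error", {
  set.seed(31)
  for (rep in 1:3) {
    pmf_a <- build_pmf(runif(400), runif(400), seq(0, 1, 0.1), seq(0, 1, 0.1))
    pmf_b <- build_pmf(runif(400)^1.3, runif(400)^0.8, seq(0, 1, 0.1),
                       seq(0, 1, 0.1))
    m <- merge_pmfs(pmf_a, pmf_b)
    ov <- m$overlap
    obj <- function(d) sum(pmf_a$rho[ov] * pmf_b$rho[ov] *
                             (pmf_a$energy[ov] - pmf_b$energy[ov] - d)^2)
    grid_d <- seq(-10, 10, 1e-4)
    best <- grid_d[which.min(vapply(grid_d, obj, numeric(1)))]
    expect_equal(m$delta, best, tolerance = 1e-3)
  }
})

test_that("merging requires shared edges and overlap", {
  pmf_a <- build_pmf(c(0.1, 0.2), c(0.1, 0.2), seq(0, 1, 0.5), seq(0, 1, 0.5))
  pmf_c <- build_pmf(c(0.1, 0.2), c(0.1, 0.2), seq(0, 2, 1), seq(0, 1, 0.5))
  expect_error(merge_pmfs(pmf_a, pmf_c), "identical bin edges")
  pmf_d <- build_pmf(0.9, 0.9, seq(0, 1, 0.5), seq(0, 1, 0.5))
  expect_error(merge_pmfs(build_pmf(0.1, 0.1, seq(0, 1, 0.5),
                                    seq(0, 1, 0.5)), pmf_d),
               "overlap")
})

test_that("pmf export writes bin table and JSON header with the shift", {
  set.seed(37)
  pmf_a <- build_pmf(runif(100), runif(100), seq(0, 1, 0.25), seq(0, 1, 0.25))
  pmf_b <- build_pmf(runif(100), runif(100), seq(0, 1, 0.25), seq(0, 1, 0.25))
  m <- merge_pmfs(pmf_a, pmf_b)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_pmf(m, csv, js)
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 16)
  hdr <- jsonlite::read_json(js)
  expect_equal(hdr$delta, m$delta, tolerance = 1e-12)
})
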