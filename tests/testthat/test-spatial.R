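test_that("wall-boundary neighborhoods have the right sizes", {
  expect_equal(nrow(neighbors(c(0, 0), c(50, 50))), 2)
  expect_equal(nrow(neighbors(c(0, 5), c(50, 50))), 3)
  expect_equal(nrow(neighbors(c(10, 10), c(50, 50))), 4)
  expect_equal(nrow(neighbors(c(49, 49), c(50, 50))), 2)
  expect_error(neighbors(c(50, 0), c(50, 50)), "out of bounds")
})

test_that("local division distribution mirrors the global form on neighbor counts", {
  p0 <- model_params(N = 9, I = 3, J = 3, mu1 = 0, muS1 = 0, muS = 0)
  lat <- lattice_tissue(3, 3, fill = 0L)
  expect_equal(unname(local_division_distribution(lat, c(1, 1), p0)),
               c(1, 0, 0, 0))

  # 2 x Type 0 and 2 x Type 1 neighbors, neutral, no mutation
  g <- matrix(0L, 3, 3)
  g[1, 2] <- 1L; g[3, 2] <- 1L  # up and down neighbors of center
  lat2 <- lattice_tissue(3, 3, grid = g)
  expect_equal(unname(local_division_distribution(lat2, c(1, 1), p0)),
               c(0.5, 0.5, 0, 0))

  # hand-evaluated mixed neighborhood: 1 x Type0, 1 x Type1, 2 x TypeS-1
  g3 <- matrix(0L, 3, 3)
  g3[1, 2] <- 0L; g3[3, 2] <- 1L; g3[2, 1] <- 2L; g3[2, 3] <- 2L
  lat3 <- lattice_tissue(3, 3, grid = g3)
  p <- model_params(N = 9, I = 3, J = 3, r1 = 1.2, rS1 = 0.8,
                    mu1 = 0.01, muS1 = 0.01, muS = 0.001)
  d <- local_division_distribution(lat3, c(1, 1), p)
  expect_equal(unname(d),
               c(1 * 0.99, 1.2 * 0.99 + 1 * 0.01,
                 1.6 * 0.999 + 1.2 * 0.01, 1.6 * 0.001) / 3.8,
               tolerance = 1e-12)
})

test_that("local and global distributions coincide on homogeneous neighborhoods", {
  # column stripes 0,1,0,1,...: every interior neighborhood is 2+2, equal
  # to the global 50/50 composition
  g <- matrix(0L, 6, 6)
  g[, c(2, 4, 6)] <- 1L
  lat <- lattice_tissue(6, 6, grid = g)
  p <- model_params(N = 36, I = 6, J = 6, r1 = 1.3,
                    mu1 = 0.02, muS1 = 0.01, muS = 0.005)
  loc <- local_division_distribution(lat, c(2, 2), p)
  glob <- division_distribution(tissue_state(18, 18, 0), p)
  expect_equal(unname(loc), unname(glob), tolerance = 1e-12)
})

test_that("spatial turnover keeps the lattice fully occupied", {
  p <- model_params(N = 25, I = 5, J = 5, r1 = 1.1, rS1 = 0.9,
                    mu1 = 0.05, muS1 = 0.05, muS = 0.05)
  set.seed(401)
  lat <- lattice_tissue(5, 5)
  for (i in 1:2000) {
    out <- spatial_turnover_step(lat, p)
    lat <- out$lattice
    expect_identical(sum(lattice_composition(lat)), 25L)
  }
  # homogeneous lattice without mutation never changes
  p0 <- model_params(N = 25, I = 5, J = 5, mu1 = 0, muS1 = 0, muS = 0)
  lat0 <- lattice_tissue(5, 5)
  for (i in 1:200) lat0 <- spatial_turnover_step(lat0, p0)$lattice
  expect_identical(unname(lattice_composition(lat0)[["X0"]]), 25L)
})

test_that("compiled spatial turnover matches the exact 2x2 hitting time", {
  exact <- lattice2x2_hitting_steps_exact()
  set.seed(402)
  steps <- locorecur:::cpp_steps_to_first_sbirth_spatial(
    2L, 2L, 20000L, 1, 1, 1, 0.1, 0.1, 0.1, 1e9, 10000L)
  se <- sd(steps) / sqrt(length(steps))
  expect_lt(abs(mean(steps) - exact), 3 * se)
})

test_that("spatial simulations censor without mutation and replay by seed", {
  p <- model_params(N = 25, I = 5, J = 5, mu1 = 0, max_time = 20)
  res <- simulate_spatial(p, seed = 1)
  expect_false(res$detected)

  p2 <- model_params(N = 25, I = 5, J = 5, mu1 = 0.05, muS1 = 0.05,
                     muS = 0.05)
  a <- simulate_spatial(p2, seed = 7)
  b <- simulate_spatial(p2, seed = 7)
  expect_identical(a, b)
  expect_identical(sum(a$composition_at_surgery), 25L)
})

test_that("the lattice preserves normal cells longer than the well-mixed tissue", {
  # standard parameter set scaled to a 20x20 lattice vs well-mixed N=400:
  # Type 0 fraction at detection should be higher with spatial structure
  n <- 60
  pw <- model_params(N = 400, rS1 = 1.2, rS = 1.5)
  ps <- model_params(N = 400, I = 20, J = 20, rS1 = 1.2, rS = 1.5)
  set.seed(403)
  f0 <- function(res) res$composition[["X0"]] / 400
  wm <- vapply(seq_len(n), function(i) f0(simulate_to_detection(pw)),
               numeric(1))
  sp <- vapply(seq_len(n), function(i)
    f0(simulate_spatial_to_detection(ps)), numeric(1))
  expect_gt(mean(sp), mean(wm))
  expect_lt(wilcox.test(sp, wm, alternative = "greater")$p.value, 0.05)
})

test_that("lattice snapshots round-trip through the plain-text grid format", {
  set.seed(404)
  g <- matrix(sample(0:2, 30, replace = TRUE), nrow = 5)
  lat <- lattice_tissue(5, 6, grid = g)
  path <- withr::local_tempfile(fileext = ".txt")
  write_lattice(lat, path)
  back <- read_lattice(path)
  expect_identical(back$grid, lat$grid)
})
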