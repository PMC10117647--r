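test_that("waiting time is the reciprocal total event rate", {
  expect_equal(waiting_time(model_params(N = 1000, d = 1), XS = 0), 0.001)
  p <- model_params(N = 1000, d = 1, rS = 1.5, dS = 1.0)
  expect_equal(waiting_time(p, XS = 1000), 1 / 3500)
  expect_error(waiting_time(model_params(N = 1000, d = 0), XS = 0),
               "frozen")
})

test_that("event channel probabilities are rate shares of the total", {
  p <- model_params(N = 1000, d = 1, rS = 1.5, dS = 1.0)
  expect_equal(unname(event_channel_probabilities(p, 0)), c(1, 0, 0))
  expect_equal(unname(event_channel_probabilities(p, 1000)),
               c(1000, 1500, 1000) / 3500)
})

test_that("division distribution reproduces the transition probabilities", {
  # pure Type 0 tissue without mutation only makes Type 0 daughters
  p0 <- model_params(N = 1000, mu1 = 0, muS1 = 0, muS = 0)
  expect_equal(unname(division_distribution(tissue_state(1000, 0, 0), p0)),
               c(1, 0, 0, 0))

  # neutral fitness, no mutation: daughter type i with probability Xi/N
  d <- division_distribution(tissue_state(500, 300, 200), p0)
  expect_equal(unname(d), c(0.5, 0.3, 0.2, 0))

  # hand-evaluated mixed case: numerators (495, 361.4, 163.44, 0.16)/1020
  p <- model_params(N = 1000, r1 = 1.2, rS1 = 0.8,
                    mu1 = 0.01, muS1 = 0.01, muS = 0.001)
  d <- division_distribution(tissue_state(500, 300, 200), p)
  expect_equal(unname(d), c(495, 361.4, 163.44, 0.16) / 1020,
               tolerance = 1e-12)

  # zero total fitness weight is an error
  pz <- model_params(N = 100, r0 = 0, r1 = 1)
  expect_error(division_distribution(tissue_state(100, 0, 0), pz),
               "no cell can divide")
})

test_that("turnover conserves tissue size and respects the redraw cap", {
  p <- model_params(N = 30, r1 = 1.1, rS1 = 0.9,
                    mu1 = 0.05, muS1 = 0.05, muS = 0.05)
  set.seed(5)
  st <- tissue_state(10, 10, 10)
  for (i in 1:2000) {
    out <- turnover_step(st, p)
    st <- out$state
    expect_identical(sum(st), 30L)
  }
  # muS = 1 with an all-S-1 tissue makes every vacancy draw malignant
  p1 <- model_params(N = 10, muS = 1, redraw_cap = 50)
  set.seed(6)
  expect_error(turnover_step(tissue_state(0, 0, 10), p1), "redraw cap")
})

test_that("deterministic growth time follows the exponential-expansion form", {
  expect_equal(deterministic_growth_time(1.5, 1.0, 1000, 1e9),
               2 * log(5e5))
  expect_equal(deterministic_growth_time(1.5, 1.0, 1000, 2000), 0)
  expect_error(deterministic_growth_time(1.0, 1.0, 1000, 1e9),
               "no net growth")
  expect_error(deterministic_growth_time(1.5, 1.0, 1000, 1000),
               "threshold")
})

test_that("surgery removes the tumor and nothing else", {
  t1 <- apply_surgery(list(XS = 1e9, t = 42))
  expect_identical(t1$XS, 0)
  expect_identical(t1$t, 42)
  expect_identical(apply_surgery(t1)$XS, 0)
})

test_that("blocked mutation pathway censors; detection conserves tissue", {
  p <- model_params(N = 50, mu1 = 0, muS1 = 0.05, muS = 0.05,
                    max_time = 50)
  res <- simulate_to_detection(p, seed = 1)
  expect_false(res$detected)
  expect_equal(res$t_detect, 50)

  p2 <- model_params(N = 50, mu1 = 0.05, muS1 = 0.05, muS = 0.05)
  res2 <- simulate_to_detection(p2, seed = 2)
  expect_true(res2$detected)
  expect_identical(sum(res2$composition), 50L)
})

test_that("full runs replay bit-identically under a fixed seed", {
  p <- model_params(N = 50, mu1 = 0.05, muS1 = 0.05, muS = 0.05)
  a <- run_full(p, seed = 11)
  b <- run_full(p, seed = 11)
  expect_identical(a, b)
  expect_true(a$detected)
  expect_true(a$t_recur > 0)
})

test_that("a censored initiation skips the recurrence phase", {
  p <- model_params(N = 50, mu1 = 0, max_time = 20)
  out <- run_full(p, seed = 3)
  expect_false(out$detected)
  expect_false(out$recurred)
  expect_true(is.na(out$t_recur))
})

test_that("Type S-1 proportion bins follow the half-open intervals", {
  expect_equal(proportion_bin(tissue_state(450, 450, 100)), "small")
  expect_equal(proportion_bin(tissue_state(250, 250, 500)), "intermediate")
  expect_equal(proportion_bin(tissue_state(50, 49, 901)), "large")
  expect_equal(proportion_bin(tissue_state(50, 50, 900)), "intermediate")
})

test_that("outcome batches export as the tab-separated contract", {
  p <- model_params(N = 50, mu1 = 0.05, muS1 = 0.05, muS = 0.05)
  outs <- lapply(1:3, function(i) run_full(p, seed = i))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_outcomes(outs, path)
  df <- read.delim(path)
  expect_equal(names(df), c("run_id", "seed", "t_detect", "X0", "X1",
                            "XS1", "t_recur", "detected", "recurred"))
  expect_equal(nrow(df), 3)
  expect_equal(df$X0 + df$X1 + df$XS1, rep(50, 3))
})
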