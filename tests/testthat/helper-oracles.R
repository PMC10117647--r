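# Exact Markov-chain oracles for the Moran tissue dynamics, built by
# enumerating the full composition (well-mixed) or lattice state space and
# solving the absorbing-chain hitting-time system. These stay independent
# of the simulation engines they are used to check.

std_params <- function(...) {
  args <- list(N = 100, rS1 = 1.2, rS = 1.5, max_time = 2000)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_params, args)
}

# Expected number of turnover events until the first malignant (Type S)
# birth in the well-mixed tissue of size N started from all Type 0.
# Per turnover event, absorption happens iff the FIRST vacancy draw is the
# malignant branch (prob rS1*XS1*muS/F); otherwise the composition moves
# by an independent (death, daughter) pair.
wm_hitting_steps_exact <- function(N, r0 = 1, r1 = 1, rS1 = 1,
                                   mu1 = 0.1, muS1 = 0.1, muS = 0.1) {
  states <- expand.grid(X0 = 0:N, X1 = 0:N, XS1 = 0:N)
  states <- states[rowSums(states) == N, , drop = FALSE]
  ns <- nrow(states)
  key <- function(s) paste(s, collapse = ",")
  idx <- stats::setNames(seq_len(ns), apply(states, 1, key))
  Q <- matrix(0, ns, ns)
  for (si in seq_len(ns)) {
    s <- as.numeric(states[si, ])
    F <- r0 * s[1] + r1 * s[2] + rS1 * s[3]
    pd <- c(r0 * s[1] * (1 - mu1),
            r1 * s[2] * (1 - muS1) + r0 * s[1] * mu1,
            rS1 * s[3] * (1 - muS) + r1 * s[2] * muS1) / F
    for (dy in 1:3) for (dau in 1:3) {
      pr <- (s[dy] / N) * pd[dau]
      if (pr > 0) {
        s2 <- s
        s2[dy] <- s2[dy] - 1
        s2[dau] <- s2[dau] + 1
        j <- idx[[key(s2)]]
        Q[si, j] <- Q[si, j] + pr
      }
    }
  }
  h <- solve(diag(ns) - Q, rep(1, ns))
  h[idx[[key(c(N, 0, 0))]]]
}

# Same hitting time on the 2 x 2 lattice (81 states; every site has
# exactly 2 in-bounds neighbors under the wall boundary).
lattice2x2_hitting_steps_exact <- function(r0 = 1, r1 = 1, rS1 = 1,
                                           mu1 = 0.1, muS1 = 0.1,
                                           muS = 0.1) {
  # sites in row-major order: (0,0), (0,1), (1,0), (1,1)
  nbrs <- list(c(2, 3), c(1, 4), c(1, 4), c(2, 3))
  states <- as.matrix(expand.grid(rep(list(0:2), 4)))
  ns <- nrow(states)
  key <- function(s) paste(s, collapse = "")
  idx <- stats::setNames(seq_len(ns), apply(states, 1, key))
  rvec <- c(r0, r1, rS1)
  Q <- matrix(0, ns, ns)
  for (si in seq_len(ns)) {
    s <- states[si, ]
    for (site in 1:4) {
      cnt <- tabulate(s[nbrs[[site]]] + 1L, nbins = 3)
      F <- sum(rvec * cnt)
      pd <- c(r0 * cnt[1] * (1 - mu1),
              r1 * cnt[2] * (1 - muS1) + r0 * cnt[1] * mu1,
              rS1 * cnt[3] * (1 - muS) + r1 * cnt[2] * muS1) / F
      for (dau in 1:3) {
        if (pd[dau] > 0) {
          s2 <- s
          s2[site] <- dau - 1L
          j <- idx[[key(s2)]]
          Q[si, j] <- Q[si, j] + 0.25 * pd[dau]
        }
      }
    }
  }
  h <- solve(diag(ns) - Q, rep(1, ns))
  h[idx[[key(c(0, 0, 0, 0))]]]
}

mean_recurrence_arm <- function(p, n) {
  ts <- vapply(seq_len(n), function(i) {
    o <- run_full(p)
    if (o$detected && o$recurred) o$t_recur else NA_real_
  }, numeric(1))
  ts[!is.na(ts)]
}

ci95 <- function(x) {
  m <- mean(x)
  half <- 1.96 * stats::sd(x) / sqrt(length(x))
  c(lo = m - half, hi = m + half)
}
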