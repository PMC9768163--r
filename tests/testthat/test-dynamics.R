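test_that("parameter validation enforces the documented ranges", {
  expect_s3_class(soam_params(), "soam_params")
  expect_error(soam_params(epsilon = 1.2), "epsilon")
  expect_error(soam_params(pi = -0.1), "pi")
  expect_error(soam_params(n = 1), "n must")
  expect_error(soam_params(n = 10, k = 20), "k must")
})

test_that("initial populations have the exact amplifier count and uniform opinions", {
  p <- soam_params(n = 100, pi = 0.2)
  st <- init_population(p, rng_stream(1))
  expect_equal(sum(st$is_amplifier), 20)
  expect_true(all(st$opinions >= -1 & st$opinions <= 1))
  expect_equal(st$strikes, integer(100))
  expect_equal(st$t, 0L)
  st0 <- init_population(soam_params(n = 100, pi = 0), rng_stream(1))
  expect_equal(sum(st0$is_amplifier), 0)
  # CLT check: per-seed mean opinion has SE 0.577/sqrt(100)
  means <- vapply(1:100, function(s) {
    mean(init_population(p, rng_stream(s))$opinions)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.06)
})

test_that("amplification draws follow the trait and probability", {
  p <- soam_params(n = 100, pi = 0.2, p = 0.5, s = 0.3)
  st <- init_population(p, rng_stream(2))
  r <- rng_stream(3)
  counts <- vapply(1:200, function(i) {
    d <- draw_step(st, p, r)
    expect_true(all(st$is_amplifier[d$amplify_now])) # implies trait
    expect_true(all(d$sigma >= 0 & d$sigma <= 0.3))
    expect_true(all(d$sigma[!d$amplify_now] == 0))
    sum(d$amplify_now)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10), 1) # Binomial(20, 0.5) mean

  p0 <- soam_params(n = 50, pi = 0.2, p = 0)
  st0 <- init_population(p0, rng_stream(2))
  expect_false(any(draw_step(st0, p0, r)$amplify_now))
  p1 <- soam_params(n = 50, pi = 1, p = 1)
  st1 <- init_population(p1, rng_stream(2))
  expect_true(all(draw_step(st1, p1, r)$amplify_now))
})

test_that("expressed opinions amplify away from zero, zero counting as positive", {
  st <- structure(list(opinions = c(-0.4, 0.0, 0.9)), class = "soam_state")
  draws <- list(amplify_now = c(TRUE, TRUE, FALSE), sigma = c(0.3, 0.2, 0))
  expect_equal(expressed_opinions(st, draws), c(-0.7, 0.2, 0.9))
})

test_that("amplification keeps sign and bounded magnitude gain", {
  p <- soam_params(n = 80, pi = 0.5, p = 0.8, s = 0.4)
  st <- init_population(p, rng_stream(4))
  r <- rng_stream(5)
  for (rep in 1:20) {
    d <- draw_step(st, p, r)
    so <- expressed_opinions(st, d)
    amp <- d$amplify_now
    expect_true(all(abs(so[amp]) >= abs(st$opinions[amp])))
    expect_true(all(abs(so[amp]) <= abs(st$opinions[amp]) + p$s))
    sgn <- function(x) ifelse(x >= 0, 1, -1) # zero counts as positive
    expect_true(all(sgn(so[amp]) == sgn(st$opinions[amp])))
    expect_equal(so[!amp], st$opinions[!amp])
    st$opinions <- stats::runif(80, -2, 2)
  }
})

test_that("influence sets gate on the inclusive confidence threshold", {
  net <- make_net(4, rbind(c(2, 1), c(3, 1), c(4, 1)))
  expressed <- c(NA, 0.2, -0.2, 0.21)
  expect_equal(influence_set(1, 0.0, expressed, net, 0.2), c(2L, 3L))
  expect_equal(influence_set(2, 0.0, expressed, net, 0.2), integer(0))
  # degenerate threshold: only exact matches
  expect_equal(influence_set(1, 0.2, expressed, net, 0), 2L)
})

test_that("a single step reproduces hand-computed averages", {
  p <- soam_params(n = 3, k = 2, epsilon = 0.8, pi = 0, t_max = 1)
  net <- make_net(3, rbind(c(2, 1), c(3, 1)))
  op <- engine_step(c(0.5, 0.3, 0.9), rep(FALSE, 3), numeric(3), net, p)
  expect_equal(op[1], (0.5 + 0.3 + 0.9) / 3)
  # neighbors gated out: opinion unchanged
  p2 <- soam_params(n = 3, k = 2, epsilon = 0.1, pi = 0, t_max = 1)
  op2 <- engine_step(c(0.5, 0.3, 0.9), rep(FALSE, 3), numeric(3), net, p2)
  expect_equal(op2[1], 0.5)
  # agents with no in-neighbors never move
  expect_equal(op[2], 0.3)
  expect_equal(op[3], 0.9)
})

test_that("the engine step matches the brute-force oracle on small fixtures", {
  set.seed(1234)
  for (rep in 1:25) {
    n <- sample(3:6, 1)
    # random directed edge set without self-loops
    pairs <- expand.grid(s = 1:n, t = 1:n)
    pairs <- pairs[pairs$s != pairs$t, ]
    keep <- stats::runif(nrow(pairs)) < 0.5
    edges <- as.matrix(pairs[keep, , drop = FALSE])
    net <- make_net(n, if (nrow(edges)) edges else matrix(integer(0), ncol = 2))
    opinions <- stats::runif(n, -1.5, 1.5)
    amplify <- stats::runif(n) < 0.4
    sigma <- ifelse(amplify, stats::runif(n, 0, 0.5), 0)
    eps <- sample(c(0.1, 0.3, 0.8), 1)
    ext <- if (rep %% 3 == 0) stats::runif(2, -1, 1) else numeric(0)
    p <- soam_params(n = n, k = 1, epsilon = eps, pi = 0.5, s = 0.5)
    got <- engine_step(opinions, amplify, sigma, net, p, externals = ext)
    want <- oracle_step(opinions, amplify, sigma, net$edges, eps, ext)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("without amplifiers on a complete network one step is the classic bounded-confidence update", {
  set.seed(77)
  for (eps in c(0.1, 0.3, 0.9)) {
    n <- 12
    net <- generate_network("complete", n = n)
    x <- stats::runif(n, -1, 1)
    p <- soam_params(n = n, k = n - 1, epsilon = eps, pi = 0,
                     network_kind = "complete")
    got <- engine_step(x, rep(FALSE, n), numeric(n), net, p)
    expect_equal(got, hk_step(x, eps), tolerance = 1e-12)
  }
})

test_that("runs without amplifiers stay inside the initial opinion hull", {
  for (s in 1:5) {
    p <- soam_params(n = 40, k = 4, epsilon = c(0.2, 0.8)[s %% 2 + 1],
                     pi = 0, t_max = 60, seed = s)
    tr <- soam_run(p)
    expect_true(all(tr$opinions >= min(tr$opinions[1, ]) - 1e-12))
    expect_true(all(tr$opinions <= max(tr$opinions[1, ]) + 1e-12))
  }
})

test_that("runs are bit-identical for a fixed seed", {
  p <- soam_params(n = 50, k = 5, epsilon = 0.4, pi = 0.3, p = 0.5, s = 0.3,
                   t_max = 80, seed = 42)
  a <- soam_run(p)
  b <- soam_run(p)
  expect_identical(a$opinions, b$opinions)
  expect_identical(a$amplified, b$amplified)
  expect_identical(a$conflict, b$conflict)
})

test_that("a zero-length run contains only the initial state", {
  p <- soam_params(n = 30, t_max = 0, seed = 9)
  tr <- soam_run(p)
  expect_equal(nrow(tr$opinions), 1)
  expect_equal(tr$conflict, conflict(tr$opinions[1, ]))
})

test_that("trajectories export to long format with stride", {
  p <- soam_params(n = 10, k = 3, t_max = 10, pi = 0.5, p = 1, s = 0.5,
                   seed = 3)
  tr <- soam_run(p)
  df <- trajectory_df(tr)
  expect_equal(nrow(df), 11 * 10)
  expect_named(df, c("timestep", "agent_id", "opinion", "amplified_flag",
                     "replaced_flag"))
  expect_equal(df$opinion[df$timestep == 10], tr$opinions[11, ])
  df3 <- trajectory_df(tr, record_every = 3)
  expect_setequal(unique(df3$timestep), c(0, 3, 6, 9, 10))
})

test_that("mismatched network and population sizes error", {
  p <- soam_params(n = 20, t_max = 5)
  net <- generate_network("complete", n = 10)
  expect_error(soam_run(p, net = net), "size")
})
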