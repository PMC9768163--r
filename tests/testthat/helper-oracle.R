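# Independent brute-force oracles, written separately from the engine:
# plain per-agent loops over the defining update rules, no shared code with
# the package's vectorized path.

# One synchronous update: expressed opinions from the t-1 opinions (amplified
# away from zero), confidence-gated averaging including the agent's own
# previous opinion, externals treated like gated neighbors.
oracle_step <- function(opinions, amplify_now, sigma, edges, epsilon,
                        externals = numeric(0)) {
  n <- length(opinions)
  so <- numeric(n)
  for (j in seq_len(n)) {
    if (amplify_now[j]) {
      so[j] <- if (opinions[j] < 0) opinions[j] - sigma[j]
               else opinions[j] + sigma[j]
    } else {
      so[j] <- opinions[j]
    }
  }
  new_op <- numeric(n)
  for (i in seq_len(n)) {
    vals <- numeric(0)
    for (j in seq_len(n)) {
      is_edge <- FALSE
      for (r in seq_len(nrow(edges))) {
        if (edges[r, 1] == j && edges[r, 2] == i) is_edge <- TRUE
      }
      if (is_edge && abs(opinions[i] - so[j]) <= epsilon) {
        vals <- c(vals, so[j])
      }
    }
    for (x in externals) {
      if (abs(opinions[i] - x) <= epsilon) vals <- c(vals, x)
    }
    new_op[i] <- (opinions[i] + sum(vals)) / (1 + length(vals))
  }
  new_op
}

# classic bounded-confidence update on a complete graph: agent i averages
# over all agents (self included) within epsilon of its own opinion
hk_step <- function(x, epsilon) {
  vapply(seq_along(x), function(i) mean(x[abs(x[i] - x) <= epsilon]),
         numeric(1))
}

# run one engine step with prescribed draws on a given state
engine_step <- function(opinions, amplify_now, sigma, net, params,
                        externals = numeric(0)) {
  state <- structure(list(opinions = opinions,
                          is_amplifier = amplify_now,
                          strikes = integer(length(opinions)), t = 0L),
                     class = "soam_state")
  draws <- list(amplify_now = amplify_now, sigma = sigma)
  out <- soam_step(state, net, params, rng_stream(1), externals = externals,
                   draws = draws)
  out$opinions
}

make_net <- function(n, edges) {
  net <- generate_network("complete", n = n)
  net$edges <- matrix(as.integer(edges), ncol = 2,
                      dimnames = list(NULL, c("source", "target")))
  net$kind <- "custom"
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a
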