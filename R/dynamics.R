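# SOAM core dynamics.
#
# Each timestep, every agent i averages its own previous opinion with the
# expressed opinions of its in-neighbors that lie within the confidence
# threshold epsilon of its own previous opinion:
#
#   O[i,t] = (O[i,t-1] + sum_{j in I} SO[j]) / (1 + |I|)
#   I      = { j in in_neighbors(i) : |O[i,t-1] - SO[j]| <= epsilon }
#
# Amplifier agents (trait E_i) amplify with probability p each timestep,
# publishing SO = O +/- sigma (away from zero), sigma ~ Uniform(0, s); all
# other agents publish SO = O. One expressed-opinion vector, computed from
# the t-1 opinions, is used both for gating and for averaging, and all agents
# update simultaneously. Opinions start uniform on [-1, 1] and are never
# clipped afterwards.

#' Model parameters
#'
#' Bundles the system-level parameters of a simulation run.
#'
#' @param n Number of agents.
#' @param k Mean links per node of the generated network.
#' @param epsilon Confidence threshold in `[0, 1]`: maximum opinion distance
#'   at which an expressed opinion can influence an agent.
#' @param pi Proportion of the population who are amplifiers, in `[0, 1]`.
#' @param p Per-timestep probability that an amplifier amplifies, in `[0, 1]`.
#' @param s Amplification strength in `[0, 1]`: upper bound of the uniform
#'   amount added to the magnitude of an expressed opinion.
#' @param t_max Number of timesteps to simulate.
#' @param network_kind Network generator, see [generate_network()].
#' @param seed Master integer seed; all randomness in a run derives from it.
#' @return A validated `soam_params` list.
#' @examples
#' soam_params(n = 100, k = 5, epsilon = 0.2, pi = 0.2, p = 0.5, s = 0.2)
#' @export
soam_params <- function(n = 100, k = 5, epsilon = 0.8, pi = 0, p = 0.5,
                        s = 0.5, t_max = 400, network_kind = "erdos_renyi",
                        seed = 1L) {
  params <- list(n = as.integer(n), k = k, epsilon = epsilon, pi = pi, p = p,
                 s = s, t_max = as.integer(t_max),
                 network_kind = match.arg(network_kind, NETWORK_KINDS),
                 seed = as.integer(seed))
  for (nm in c("epsilon", "pi", "p", "s")) {
    v <- params[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("%s must be a single value in [0, 1]", nm), call. = FALSE)
    }
  }
  if (params$n < 2) stop("n must be at least 2", call. = FALSE)
  if (params$k < 0 || params$k > params$n - 1) {
    stop("k must satisfy 0 <= k <= n - 1", call. = FALSE)
  }
  if (params$t_max < 0) stop("t_max must be non-negative", call. = FALSE)
  structure(params, class = "soam_params")
}

#' Initialize a population
#'
#' Draws i.i.d. uniform opinions on `[-1, 1]` and flags exactly
#' `round(pi * n)` agents, chosen uniformly without replacement, as
#' amplifiers. Strike counts start at zero.
#'
#' @param params A [soam_params()] object.
#' @param rng A [rng_stream()].
#' @return A `soam_state`: list with `opinions`, `is_amplifier`, `strikes`,
#'   and the current timestep `t` (0).
#' @export
init_population <- function(params, rng) {
  n <- params$n
  opinions <- stream_runif(rng, n, -1, 1)
  n_amp <- as.integer(round(params$pi * n))
  is_amplifier <- logical(n)
  if (n_amp > 0) is_amplifier[stream_sample(rng, seq_len(n), n_amp)] <- TRUE
  structure(list(opinions = opinions, is_amplifier = is_amplifier,
                 strikes = integer(n), t = 0L),
            class = "soam_state")
}

#' Draw per-timestep amplification events
#'
#' Each amplifier amplifies this timestep with probability `p` (a fresh
#' uniform draw per agent per timestep); non-amplifiers never do. Amplifying
#' agents get an amplification amount `sigma` drawn uniform on `[0, s]`;
#' everyone else gets zero.
#'
#' @inheritParams init_population
#' @param state A `soam_state`.
#' @return List with logical `amplify_now` and numeric `sigma`, both length n.
#' @export
draw_step <- function(state, params, rng) {
  n <- length(state$opinions)
  p_draw <- stream_runif(rng, n)
  amplify_now <- state$is_amplifier & (p_draw <= params$p)
  # draw a full vector so the stream advances by a fixed amount per timestep
  sigma <- stream_runif(rng, n, 0, params$s)
  sigma[!amplify_now] <- 0
  list(amplify_now = amplify_now, sigma = sigma)
}

#' Expressed opinions
#'
#' The opinion each agent publishes this timestep: the actual opinion pushed
#' away from zero by `sigma` for agents amplifying now (negative opinions get
#' more negative, non-negative ones more positive), the actual opinion
#' unchanged for everyone else.
#'
#' @param state A `soam_state` (opinions at t-1).
#' @param draws Output of [draw_step()].
#' @return Numeric vector of published opinions.
#' @export
expressed_opinions <- function(state, draws) {
  so <- state$opinions
  amp <- draws$amplify_now
  neg <- amp & so < 0
  pos <- amp & so >= 0
  so[neg] <- so[neg] - draws$sigma[neg]
  so[pos] <- so[pos] + draws$sigma[pos]
  so
}

#' Confidence-gated influence set
#'
#' The in-neighbors of agent `i` whose expressed opinion lies within
#' `epsilon` of `i`'s own (previous) opinion; the boundary is inclusive.
#' The agent itself is never a member (its own previous opinion enters the
#' update separately).
#'
#' @param i Node id.
#' @param own_opinion Agent `i`'s opinion at the previous timestep.
#' @param expressed Vector of expressed opinions for all agents.
#' @param net A `soam_network`.
#' @param epsilon Confidence threshold.
#' @return Integer vector of influencing node ids.
#' @export
influence_set <- function(i, own_opinion, expressed, net, epsilon) {
  nb <- in_neighbors(net, i)
  nb[abs(own_opinion - expressed[nb]) <= epsilon]
}

# Vectorized synchronous update over the edge list. `externals` are extra
# opinions visible to every agent, gated by epsilon like neighbor opinions
# and counted in the denominator.
update_opinions <- function(op, so, src, tgt, epsilon, externals = numeric(0)) {
  n <- length(op)
  sums <- numeric(n)
  cnt <- numeric(n)
  if (length(src) > 0) {
    ok <- abs(op[tgt] - so[src]) <= epsilon
    if (any(ok)) {
      rs <- rowsum(so[src[ok]], tgt[ok])
      sums[as.integer(rownames(rs))] <- rs[, 1]
      cnt <- tabulate(tgt[ok], nbins = n)
    }
  }
  if (length(externals) > 0) {
    within <- abs(outer(op, externals, "-")) <= epsilon
    sums <- sums + as.vector(within %*% externals)
    cnt <- cnt + rowSums(within)
  }
  (op + sums) / (1 + cnt)
}

#' Advance the population by one timestep
#'
#' Performs one synchronous update: expressed opinions are computed from the
#' current (t-1) opinions, then every agent moves to the mean of its own
#' previous opinion and the confidence-gated expressed opinions it can see.
#' Strike counts increase by one for each agent that amplified. Agents with
#' an empty influence set keep their opinion.
#'
#' @inheritParams init_population
#' @param net A `soam_network` with `n_nodes == params$n`.
#' @param externals Optional numeric vector of external opinions shown to
#'   every agent this timestep (see [external_opinions()]).
#' @param draws Amplification draws for this timestep; drawn from `rng` via
#'   [draw_step()] when `NULL`. Supplying them lets a caller veto individual
#'   amplifications (the five-strike rule) before the update.
#' @return The updated `soam_state`; the draws actually applied are attached
#'   as attribute `"draws"`.
#' @export
soam_step <- function(state, net, params, rng, externals = numeric(0),
                      draws = NULL) {
  if (net$n_nodes != length(state$opinions)) {
    stop("network size does not match population size", call. = FALSE)
  }
  if (is.null(draws)) draws <- draw_step(state, params, rng)
  so <- expressed_opinions(state, draws)
  e <- net$edges
  state$opinions <- update_opinions(state$opinions, so, e[, 1], e[, 2],
                                    params$epsilon, externals)
  state$strikes <- state$strikes + as.integer(draws$amplify_now)
  state$t <- state$t + 1L
  attr(state, "draws") <- draws
  state
}

#' Run a full simulation
#'
#' Iterates [soam_step()] for `t_max` timesteps from a fresh population,
#' applying any configured interventions: balanced-opinion dissemination
#' supplies external opinions before a step; the five-strike rule suppresses
#' over-limit amplifications and replaces the offending agents at the end of
#' the timestep. Fully reproducible from `params$seed` via independent named
#' RNG substreams, so the base dynamics are identical with and without
#' interventions.
#'
#' @param params A [soam_params()] object.
#' @param net Optional pre-built `soam_network`; generated from
#'   `params$network_kind` when `NULL`.
#' @param interventions Optional [intervention_config()].
#' @return A `soam_trajectory`: list with `opinions` (a `(t_max + 1) x n`
#'   matrix, row `t + 1` holding opinions at timestep `t`), logical matrices
#'   `amplified` and `replaced` of the same shape, the `conflict` series
#'   (population SD of opinions per timestep), and the inputs (`params`,
#'   `interventions`, `net`).
#' @examples
#' tr <- soam_run(soam_params(n = 50, t_max = 50, epsilon = 0.8, seed = 7))
#' tail(tr$conflict, 1)
#' @export
soam_run <- function(params, net = NULL, interventions = NULL) {
  stopifnot(inherits(params, "soam_params"))
  if (!is.null(interventions)) validate_intervention(interventions)
  n <- params$n
  t_max <- params$t_max
  if (is.null(net)) {
    net <- generate_network(params$network_kind, n, params$k,
                            seed = derive_seed(params$seed, "network"))
  }
  if (net$n_nodes != n) stop("network size does not match params$n",
                             call. = FALSE)
  init_rng <- rng_stream(derive_seed(params$seed, "init"))
  dyn_rng <- rng_stream(derive_seed(params$seed, "dynamics"))
  int_rng <- rng_stream(derive_seed(params$seed, "interventions"))

  state <- init_population(params, init_rng)
  opinions <- matrix(NA_real_, nrow = t_max + 1, ncol = n)
  amplified <- matrix(FALSE, nrow = t_max + 1, ncol = n)
  replaced <- matrix(FALSE, nrow = t_max + 1, ncol = n)
  opinions[1, ] <- state$opinions

  max_amp <- interventions$max_amplify
  src <- net$edges[, 1]
  tgt <- net$edges[, 2]

  for (t in seq_len(t_max)) {
    draws <- draw_step(state, params, dyn_rng)
    exceeded <- integer(0)
    if (!is.null(max_amp)) {
      blocked <- draws$amplify_now & state$strikes >= max_amp
      if (any(blocked)) {
        # the over-limit amplification is not expressed; the agent is
        # replaced at the end of this timestep
        draws$amplify_now[blocked] <- FALSE
        draws$sigma[blocked] <- 0
        exceeded <- which(blocked)
      }
    }
    ext <- external_opinions(t, interventions, int_rng)
    so <- expressed_opinions(state, draws)
    state$opinions <- update_opinions(state$opinions, so, src, tgt,
                                      params$epsilon, ext)
    state$strikes <- state$strikes + as.integer(draws$amplify_now)
    state$t <- t
    if (length(exceeded) > 0) {
      state <- apply_five_strike(state, params, interventions, int_rng,
                                 exceeded = exceeded)
      replaced[t + 1, exceeded] <- TRUE
    }
    opinions[t + 1, ] <- state$opinions
    amplified[t + 1, ] <- draws$amplify_now
  }

  structure(list(opinions = opinions, amplified = amplified,
                 replaced = replaced,
                 conflict = apply(opinions, 1, conflict),
                 params = params, interventions = interventions, net = net),
            class = "soam_trajectory")
}

#' @export
print.soam_trajectory <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<soam_trajectory> n=%d t_max=%d eps=%.2f pi=%.2f p=%.2f s=%.2f (%s)\n",
    p$n, p$t_max, p$epsilon, p$pi, p$p, p$s, p$network_kind))
  cat(sprintf("  final conflict %.4f, max |opinion| %.3f, %d replacements\n",
              x$conflict[length(x$conflict)], max(abs(x$opinions)),
              sum(x$replaced)))
  invisible(x)
}

#' Trajectory as a long-format data frame
#'
#' @param traj A `soam_trajectory`.
#' @param record_every Keep every `record_every`-th timestep (timestep 0 and
#'   the final timestep are always kept).
#' @return Data frame with columns `timestep`, `agent_id`, `opinion`,
#'   `amplified_flag`, `replaced_flag`.
#' @export
trajectory_df <- function(traj, record_every = 1) {
  t_max <- nrow(traj$opinions) - 1
  keep_t <- unique(c(seq(0, t_max, by = record_every), t_max))
  rows <- keep_t + 1
  n <- ncol(traj$opinions)
  data.frame(
    timestep = rep(keep_t, times = n),
    agent_id = rep(seq_len(n), each = length(keep_t)),
    opinion = as.vector(traj$opinions[rows, ]),
    amplified_flag = as.vector(traj$amplified[rows, ]),
    replaced_flag = as.vector(traj$replaced[rows, ])
  )
}
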