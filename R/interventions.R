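# Polarization-countering interventions.
#
# Two mechanisms, modelled on moderation practices of real platforms:
# a strike rule that replaces any agent amplifying more than a fixed number
# of times, and scheduled dissemination of balanced (non-polarized) opinions
# to the whole population.

#' Configure interventions
#'
#' @param max_amplify Lifetime amplification limit per agent, or `NULL` to
#'   disable the strike rule. With the default 5, an agent attempting a 6th
#'   amplification has it suppressed and is replaced at the end of that
#'   timestep by a fresh agent (random opinion on `[-1, 1]`, amplifier trait
#'   redrawn with probability `pi`, strikes reset; node id and edges kept, so
#'   the population size is constant).
#' @param dissemination `NULL`, `TRUE` for the defaults, or a list with any
#'   of `message_count` (default 5), `period` (default 2 timesteps), `low`
#'   and `high` (default `[-1, 1]`): every `period` timesteps, starting at
#'   `t = period`, `message_count` uniform draws on `[low, high]` are shown
#'   to every agent, subject to the same confidence gating as neighbor
#'   opinions.
#' @return An `intervention_config` list.
#' @examples
#' intervention_config(max_amplify = 5)
#' intervention_config(dissemination = list(message_count = 10, period = 1))
#' @export
intervention_config <- function(max_amplify = NULL, dissemination = NULL) {
  if (isTRUE(dissemination)) dissemination <- list()
  if (!is.null(dissemination)) {
    d <- list(message_count = 5L, period = 2L, low = -1, high = 1)
    d[names(dissemination)] <- dissemination
    d$message_count <- as.integer(d$message_count)
    d$period <- as.integer(d$period)
    dissemination <- d
  }
  cfg <- structure(list(max_amplify = max_amplify,
                        dissemination = dissemination),
                   class = "intervention_config")
  validate_intervention(cfg)
}

validate_intervention <- function(cfg) {
  if (!is.null(cfg$max_amplify) && cfg$max_amplify < 1) {
    stop("max_amplify must be at least 1", call. = FALSE)
  }
  d <- cfg$dissemination
  if (!is.null(d)) {
    if (d$message_count < 0) stop("message_count must be >= 0", call. = FALSE)
    if (d$period < 1) stop("period must be >= 1", call. = FALSE)
    if (d$low > d$high) stop("low must not exceed high", call. = FALSE)
  }
  invisible(cfg)
}

#' External balanced opinions for one timestep
#'
#' On scheduled timesteps (`t` a positive multiple of `period`) returns
#' `message_count` i.i.d. uniform draws on `[low, high]`; otherwise an empty
#' vector. Every agent sees the same set that timestep.
#'
#' @param t Current timestep (1-based within a run).
#' @param cfg An [intervention_config()] (or `NULL`: no messages).
#' @param rng A [rng_stream()].
#' @return Numeric vector of external opinions (possibly empty).
#' @export
external_opinions <- function(t, cfg, rng) {
  d <- cfg$dissemination
  if (is.null(d) || d$message_count == 0) return(numeric(0))
  if (t >= d$period && t %% d$period == 0) {
    stream_runif(rng, d$message_count, d$low, d$high)
  } else {
    numeric(0)
  }
}

#' Replace agents that exceeded the amplification limit
#'
#' Each replaced agent keeps its node id and network edges but receives a
#' fresh uniform opinion on `[-1, 1]`, an amplifier flag redrawn Bernoulli
#' with the population proportion `pi`, and a zero strike count.
#'
#' @inheritParams external_opinions
#' @param state A `soam_state`.
#' @param params A [soam_params()] object.
#' @param exceeded Indices of agents to replace; defaults to every agent
#'   whose strike count exceeds `cfg$max_amplify`.
#' @return The updated `soam_state`.
#' @export
apply_five_strike <- function(state, params, cfg, rng,
                              exceeded = which(state$strikes > cfg$max_amplify)) {
  if (is.null(cfg$max_amplify)) stop("max_amplify is not set", call. = FALSE)
  m <- length(exceeded)
  if (m == 0) return(state)
  state$opinions[exceeded] <- stream_runif(rng, m, -1, 1)
  state$is_amplifier[exceeded] <- stream_runif(rng, m) < params$pi
  state$strikes[exceeded] <- 0L
  state
}
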