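# Population opinion summaries.

#' Population conflict
#'
#' Conflict at a timestep is the population standard deviation (denominator
#' `n`, not `n - 1`) of the actual opinions. A population initialized
#' uniform on `[-1, 1]` has expected conflict `1/sqrt(3) = 0.577`.
#'
#' @param opinions Numeric vector of actual opinions.
#' @return Non-negative scalar.
#' @examples
#' conflict(c(-1, 1)) # 1
#' @export
conflict <- function(opinions) {
  if (length(opinions) == 0) stop("empty opinion vector", call. = FALSE)
  sqrt(mean((opinions - mean(opinions))^2))
}

#' Opinion range
#'
#' @inheritParams conflict
#' @return Named numeric vector `c(min = , max = )`.
#' @export
opinion_range <- function(opinions) {
  if (length(opinions) == 0) stop("empty opinion vector", call. = FALSE)
  c(min = min(opinions), max = max(opinions))
}

#' Fraction of agents beyond a bound
#'
#' The fraction of agents with `|opinion| > bound`; with `bound = 1` this is
#' the fraction outside the initial opinion range (the extreme-polarized
#' share).
#'
#' @inheritParams conflict
#' @param bound Positive threshold.
#' @return Value in `[0, 1]`.
#' @export
extremity_fraction <- function(opinions, bound = 1) {
  if (bound <= 0) stop("bound must be positive", call. = FALSE)
  mean(abs(opinions) > bound)
}

#' Count opinion clusters
#'
#' Sorts the opinions and opens a new cluster wherever two consecutive
#' values differ by more than `gap`. Descriptive only; invariant to input
#' order.
#'
#' @inheritParams conflict
#' @param gap Positive split threshold (default 0.1).
#' @return Integer cluster count.
#' @export
count_clusters <- function(opinions, gap = 0.1) {
  if (gap <= 0) stop("gap must be positive", call. = FALSE)
  if (length(opinions) == 0) return(0L)
  1L + sum(diff(sort(opinions)) > gap)
}

# per-run scalar summary used by the experiment layer
summarize_trajectory <- function(traj) {
  final <- traj$opinions[nrow(traj$opinions), ]
  list(
    final_conflict = conflict(final),
    max_conflict = max(traj$conflict),
    max_abs_opinion = max(abs(traj$opinions)),
    final_max_abs_opinion = max(abs(final)),
    extremity_1 = extremity_fraction(final, 1),
    extremity_2 = extremity_fraction(final, 2),
    n_clusters = count_clusters(final),
    n_replacements = sum(traj$replaced)
  )
}
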