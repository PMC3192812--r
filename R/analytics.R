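## Closed-form quantities: single-polymerase exit probability, unimolecular
## half-life, and the median completion time of an m-stage (Erlang) process.

#' Probability of exiting on the post-transcriptional pathway
#'
#' A lone polymerase facing `n_choices` consecutive sections, on each of which
#' the hop onward (rate `k_elong`) competes with the transition to the
#' co-transcriptional splicing track (rate `k_elong / eta`), exits without
#' transitioning with probability `(eta / (eta + 1))^n_choices`. The
#' elongation rate cancels: only the odds `eta : 1` matter.
#'
#' @param eta Ratio constant (> 0).
#' @param n_choices Number of sections on which the choice exists.
#' @return Probability in `[0, 1]`.
#' @examples
#' p_post(11.39)        # ~0.122: 12% post-, 88% co-transcriptional
#' 1 - p_post(30)       # ~0.56 co-transcriptional in the 3'SS mutant
#' @export
p_post <- function(eta, n_choices = 25L) {
  if (!is.numeric(eta) || any(eta <= 0)) stop("eta must be > 0")
  if (n_choices < 0) stop("n_choices must be >= 0")
  (eta / (eta + 1))^n_choices
}

#' Half-life of a first-order reaction
#'
#' Time for a species consumed by a unimolecular reaction at rate `k` to
#' reduce by half: `log(2) / k`. For a feedback reaction with enzyme count Y,
#' the effective rate is `k * Y`, so the half-life shrinks by the factor Y.
#'
#' @param k Rate constant (/s), > 0.
#' @return Half-life in seconds.
#' @examples
#' half_life(0.0063)        # first splicing event, ~110 s
#' half_life(0.0063 * 20)   # after 19 feedback increments, ~5.5 s
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(k <= 0)) stop("k must be > 0")
  log(2) / k
}

#' Median completion time of an m-stage identical-rate process
#'
#' The waiting time through `m` sequential exponential stages, each at rate
#' `r`, is Erlang(m, r) distributed (a gamma distribution, not exponential).
#' This returns its median -- the time for an isolated cohort of molecules
#' entering the process together to reduce by half -- found by root-finding on
#' the survival function. Scales as `1/r`; `erlang_half_time(1, k)` equals
#' `half_life(k)`.
#'
#' @param m Number of stages (>= 1).
#' @param r Per-stage rate (/s), > 0.
#' @return Median waiting time in seconds.
#' @examples
#' erlang_half_time(5, 1)           # ~4.671
#' erlang_half_time(5, 4.6709 / 35) # ~35 s, the pre-mRNA 3' maturation time
#' @export
erlang_half_time <- function(m, r) {
  if (!is.numeric(m) || m < 1 || m != round(m)) stop("m must be an integer >= 1")
  if (!is.numeric(r) || r <= 0) stop("r must be > 0")
  if (m == 1) return(log(2) / r)
  f <- function(t) stats::pgamma(t, shape = m, rate = r) - 0.5
  stats::uniroot(f, lower = 0, upper = 10 * m / r, tol = 1e-10 / r)$root
}
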