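#' @name ghost_sampling
#' @title Ghost donor sampling rule
#'
#' @description
#' A ghost donor is attached to a sister branch drawn from the FECA-LECA
#' branch space. Its birth age \eqn{g} (the divergence from the sampled
#' sister, i.e. the age that would be inferred for the transfer in the
#' ghost's absence) is drawn uniformly on
#' \eqn{(\max(\mathrm{death}, \mathrm{LECA}),\ \mathrm{birth}]}
#' of the sister branch, and the transfer age \eqn{\tau} uniformly on
#' \eqn{(\mathrm{LECA},\ \min(g, \mathrm{FECA}))}: the transfer must fall
#' inside the acceptor window and cannot predate the ghost's origin. This
#' single rule covers all the case distinctions that arise from how the
#' sister branch overlaps the window:
#' \itemize{
#'   \item branch spans the whole window: \eqn{g \sim U(\mathrm{LECA}, \mathrm{birth}]};
#'   \item branch born before FECA, dead inside the window:
#'     \eqn{g \sim U(\mathrm{death}, \mathrm{birth}]};
#'   \item branch born inside the window: \eqn{g \sim U(\mathrm{LECA}, \mathrm{birth}]};
#'   \item whenever \eqn{g} falls older than FECA, \eqn{\tau \sim U(\mathrm{LECA}, \mathrm{FECA})}.
#' }
#' Endpoint inclusion is immaterial for continuous uniforms; the convention
#' is half-open `(low, high]`. The ghost's death time is a formalism (it may
#' be extinct or merely unsampled) and is never drawn.
NULL

# vectorized core: draw n ghosts on the branches at rows `idx` of the space
sample_ghosts_vec <- function(space, idx, n = length(idx)) {
  br <- space$branches
  w <- space$window
  birth <- br$birth_age[idx]
  lo_g <- pmax(br$death_age[idx], w$leca_age)
  if (any(lo_g >= birth))
    stop_input("empty ghost-birth sampling interval; branch not eligible for this window")
  g <- lo_g + stats::runif(n) * (birth - lo_g)
  hi_t <- pmin(g, w$feca_age)
  tau <- w$leca_age + stats::runif(n) * (hi_t - w$leca_age)
  data.frame(branch_id = br$branch_id[idx],
             clade_label = br$clade_label[idx],
             ghost_birth = g,
             transfer_age = tau,
             observed_age = g,
             stringsAsFactors = FALSE)
}

#' Simulate one ghost donor and its transfer
#'
#' Draws a ghost birth age and a transfer age on the given sister branch,
#' following the sampling rule described in [ghost_sampling]. The observed
#' age (the age inferred when the donor is a ghost) equals the ghost birth.
#'
#' @param branch A single-row data.frame (one [branch_records()] row), or a
#'   `branch_space` of size one.
#' @param window An `acceptor_window`; ignored (taken from the space) if
#'   `branch` is a `branch_space`.
#' @return A one-row data.frame with columns `branch_id`, `clade_label`,
#'   `ghost_birth`, `transfer_age`, `observed_age`. Uses the current RNG
#'   state; call `set.seed()` for reproducibility.
#' @export
sample_ghost <- function(branch, window = NULL) {
  space <- if (inherits(branch, "branch_space")) branch
           else build_branch_space(branch, window)
  if (nrow(space$branches) != 1L)
    stop_input("sample_ghost expects exactly one branch; use sample_pair on a space")
  sample_ghosts_vec(space, 1L)
}

#' Simulate a pair of ghost donors
#'
#' Chooses two sister branches independently and uniformly at random from
#' the branch space, with replacement (both ghosts may share one sister),
#' and draws a ghost and transfer on each.
#'
#' @param space A `branch_space`.
#' @return A two-row data.frame as in [sample_ghost()], one row per pair
#'   member. Uses the current RNG state.
#' @export
sample_pair <- function(space) {
  stopifnot(inherits(space, "branch_space"))
  idx <- sample.int(nrow(space$branches), 2L, replace = TRUE)
  sample_ghosts_vec(space, idx)
}

# Deterministic substream derivation: round r of master seed s gets its own
# seed, so per-round results are order-independent. Constants are the
# MINSTD multiplier and Knuth's multiplicative hash; arithmetic stays exact
# in doubles (< 2^53).
derive_seed <- function(master_seed, round) {
  s <- (abs(as.numeric(master_seed)) %% 2147483647) + 1
  h <- (s * 48271 + as.numeric(round) * 2654435761) %% 2147483647
  as.integer(h)
}
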