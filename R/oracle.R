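# Independent brute-force verifier for the shift probability.
#
# Deliberately shares no sampling code with the main simulator: ghost births
# and transfers are drawn by literal transcription of the case rules, one
# explicit case per branch/window configuration, so the two routes can
# cross-check each other.

#' Brute-force shift-probability oracle
#'
#' Estimates the probability that a pair of simulated transfers is shifted,
#' by direct Monte Carlo from the sampling-rule definitions. Independent of
#' the main simulator ([run_round()] and friends); intended as a validation
#' oracle.
#'
#' @param fixture A `fixture_spec` (see [fixture_spec()]).
#' @param branch_pair Optional integer vector of length 2 indexing fixture
#'   branches: condition on these two donors (in order member 1, member 2).
#'   If `NULL`, each member's donor is drawn uniformly with replacement.
#' @param p_ghost Probability that a donor is a ghost; either a single value
#'   or a length-2 vector (per member). A sampled (non-ghost) donor's
#'   observed age is the transfer age itself.
#' @param n_draws Number of pair draws (>= 1000; fewer is too noisy to be a
#'   meaningful oracle).
#' @param seed Integer seed (mandatory).
#' @return A list with `estimate`, `se` (binomial standard error), and
#'   `n_draws`.
#' @export
shift_probability_oracle <- function(fixture, branch_pair = NULL, p_ghost = 1,
                                     n_draws = 1e5, seed) {
  stopifnot(inherits(fixture, "fixture_spec"))
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1000L)
    stop_input("n_draws must be >= 1000 for a meaningful oracle")
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  p_ghost <- rep_len(as.numeric(p_ghost), 2L)
  if (anyNA(p_ghost) || any(p_ghost < 0 | p_ghost > 1))
    stop_input("p_ghost must lie in [0, 1]")
  feca <- fixture$feca; leca <- fixture$leca
  br <- fixture$branches
  nb <- nrow(br)
  if (!is.null(branch_pair)) {
    branch_pair <- as.integer(branch_pair)
    if (length(branch_pair) != 2L || anyNA(branch_pair) ||
        any(branch_pair < 1L | branch_pair > nb))
      stop_input("branch_pair must index two fixture branches")
  }

  set.seed(as.integer(seed))
  # With a fixed branch_pair, each member's stream is keyed to its branch
  # (and occurrence, for same-branch pairs), not to its slot: swapping the
  # two branches then reproduces the identical pair set, so the estimate is
  # exactly symmetric in the branch-pair argument.
  draw_member <- function(member) {
    p <- p_ghost[member]
    if (is.null(branch_pair)) {
      i <- sample.int(nb, n_draws, replace = TRUE)
    } else {
      b <- branch_pair[member]
      occ <- if (member == 2L && branch_pair[1L] == branch_pair[2L]) 2L else 1L
      set.seed(as.integer((as.numeric(seed) * 7 + b * 1000003 + occ) %% 2147483647))
      i <- rep.int(b, n_draws)
    }
    birth <- br$birth[i]; death <- br$death[i]
    # ghost birth, case by case on the branch/window configuration
    spans <- birth >= feca & death <= leca
    died_inside <- birth >= feca & death > leca
    born_inside <- birth < feca
    g <- numeric(n_draws)
    g[spans] <- stats::runif(sum(spans), leca, birth[spans])
    g[died_inside] <- stats::runif(sum(died_inside),
                                   death[died_inside], birth[died_inside])
    g[born_inside] <- stats::runif(sum(born_inside),
                                   pmax(death[born_inside], leca),
                                   birth[born_inside])
    # transfer: inside the window, never older than the ghost birth
    tau <- numeric(n_draws)
    pre_feca <- g > feca
    tau[pre_feca] <- stats::runif(sum(pre_feca), leca, feca)
    tau[!pre_feca] <- stats::runif(sum(!pre_feca), leca, g[!pre_feca])
    is_ghost <- stats::runif(n_draws) < p
    list(tau = tau, obs = ifelse(is_ghost, g, tau))
  }
  m1 <- draw_member(1L)
  m2 <- draw_member(2L)
  shifted <- (m1$tau - m2$tau) * (m1$obs - m2$obs) < 0
  est <- mean(shifted)
  list(estimate = est,
       se = sqrt(est * (1 - est) / n_draws),
       n_draws = n_draws)
}
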