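#' Classify a pair of simulated transfers
#'
#' Orders the two members by true transfer age and by observed age (the age
#' inferred in the ghost's absence). The pair is a "shift" when the two
#' orderings are strictly reversed; ties in either ordering count as no
#' shift. For shifted pairs, `outside_window` flags whether any observed age
#' predates FECA — such inferences would be discarded as artifactual in
#' practice, so a shifted pair is "confounding" only when it stays inside
#' the window.
#'
#' @param pair A two-row data.frame as returned by [sample_pair()].
#' @param window An `acceptor_window`.
#' @return A list with `true_early` and `observed_early` (member index, 1
#'   or 2, of the older event; ties resolve to 1), `is_shift`, and
#'   `outside_window` (FALSE for unshifted pairs).
#' @export
classify_pair <- function(pair, window) {
  stopifnot(inherits(window, "acceptor_window"))
  if (!is.data.frame(pair) || nrow(pair) != 2L)
    stop_input("pair must be a two-row data.frame of ghost transfers")
  cl <- classify_vec(pair$transfer_age[1L], pair$observed_age[1L],
                     pair$transfer_age[2L], pair$observed_age[2L],
                     window$feca_age)
  lapply(cl, function(v) v[1L])
}

# vectorized pair classification over parallel member vectors
classify_vec <- function(tau1, obs1, tau2, obs2, feca_age) {
  d_true <- tau1 - tau2
  d_obs <- obs1 - obs2
  is_shift <- (d_true * d_obs) < 0           # strict reversal; ties -> no shift
  list(true_early = ifelse(d_true >= 0, 1L, 2L),
       observed_early = ifelse(d_obs >= 0, 1L, 2L),
       is_shift = is_shift,
       outside_window = is_shift & (pmax(obs1, obs2) > feca_age))
}

# draw n_pairs ghost pairs as two parallel member tables
draw_pairs_vec <- function(space, n_pairs) {
  nb <- nrow(space$branches)
  idx1 <- sample.int(nb, n_pairs, replace = TRUE)
  idx2 <- sample.int(nb, n_pairs, replace = TRUE)
  list(m1 = sample_ghosts_vec(space, idx1),
       m2 = sample_ghosts_vec(space, idx2))
}

#' Run one simulation round
#'
#' Simulates `n_pairs` independent pairs of ghost transfers on the branch
#' space, classifies each pair, and summarises the proportions. The
#' confounding proportion is `shift * (1 - outside_given_shift)`: pairs that
#' are both shifted and would survive the outside-FECA filter.
#'
#' @param space A `branch_space`.
#' @param n_pairs Number of transfer pairs (>= 1).
#' @param seed Optional integer seed for this round; if `NULL`, the current
#'   RNG state is used.
#' @param keep_audit Keep the per-pair table in the result?
#' @return A list of class `round_summary`: `n_pairs`, `shift_proportion`,
#'   `outside_given_shift` (`NA` if the round produced no shifts),
#'   `confounding_proportion`, and optionally `audit`.
#' @export
run_round <- function(space, n_pairs, seed = NULL, keep_audit = FALSE) {
  stopifnot(inherits(space, "branch_space"))
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop_input("n_pairs must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  pr <- draw_pairs_vec(space, n_pairs)
  cl <- classify_vec(pr$m1$transfer_age, pr$m1$observed_age,
                     pr$m2$transfer_age, pr$m2$observed_age,
                     space$window$feca_age)
  n_shift <- sum(cl$is_shift)
  out <- list(
    n_pairs = n_pairs,
    shift_proportion = n_shift / n_pairs,
    outside_given_shift = if (n_shift == 0L) NA_real_ else
      sum(cl$outside_window) / n_shift,
    confounding_proportion = if (n_shift == 0L) 0 else
      (n_shift - sum(cl$outside_window)) / n_pairs)
  if (keep_audit)
    out$audit <- data.frame(
      pair = seq_len(n_pairs),
      branch_id_1 = pr$m1$branch_id, clade_1 = pr$m1$clade_label,
      ghost_birth_1 = pr$m1$ghost_birth, transfer_age_1 = pr$m1$transfer_age,
      observed_age_1 = pr$m1$observed_age,
      branch_id_2 = pr$m2$branch_id, clade_2 = pr$m2$clade_label,
      ghost_birth_2 = pr$m2$ghost_birth, transfer_age_2 = pr$m2$transfer_age,
      observed_age_2 = pr$m2$observed_age,
      is_shift = cl$is_shift, outside_window = cl$outside_window,
      stringsAsFactors = FALSE)
  class(out) <- "round_summary"
  out
}

#' @export
print.round_summary <- function(x, ...) {
  cat(sprintf("Round of %d pairs: shift %.4f, outside FECA | shift %s, confounding %.4f\n",
              x$n_pairs, x$shift_proportion,
              ifelse(is.na(x$outside_given_shift), "-",
                     sprintf("%.4f", x$outside_given_shift)),
              x$confounding_proportion))
  invisible(x)
}

#' Run a full replicated simulation experiment
#'
#' Repeats [run_round()] `n_rounds` times; round `r` uses an independent RNG
#' substream derived deterministically from `(seed, r)`, so results are
#' reproducible and independent of execution order. Summaries are pooled by
#' unweighted means across rounds (with equal `n_pairs` per round this
#' equals pooling pairs); rounds with zero shifts contribute no value to the
#' outside-FECA proportion.
#'
#' @param space A `branch_space`.
#' @param n_rounds Number of rounds (>= 1).
#' @param n_pairs Pairs per round.
#' @param seed Master seed (mandatory: all randomness derives from it).
#' @param keep_audit Keep per-pair tables (needed by [pair_matrix()])?
#' @return Object of class `ghost_experiment`: `rounds` (per-round
#'   data.frame), `pooled` (mean proportions), `quantiles` (2.5/25/50/75/
#'   97.5% across rounds), the `window`, call parameters, and optionally
#'   `audit` (pair-level table with a `round` column).
#' @examples
#' fx <- make_fixture_space(fixture_spec(
#'   feca = 2.42, leca = 1.89,
#'   branches = data.frame(birth = 2.42, death = 0, label = "S")))
#' ex <- run_experiment(fx, n_rounds = 20, n_pairs = 200, seed = 1)
#' ex$pooled["shift_proportion"]  # close to the analytic 0.25
#' @export
run_experiment <- function(space, n_rounds, n_pairs, seed, keep_audit = FALSE) {
  stopifnot(inherits(space, "branch_space"))
  n_rounds <- as.integer(n_rounds)
  if (is.na(n_rounds) || n_rounds < 1L) stop_input("n_rounds must be >= 1")
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  res <- vector("list", n_rounds)
  audits <- if (keep_audit) vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    rs <- run_round(space, n_pairs, seed = derive_seed(seed, r),
                    keep_audit = keep_audit)
    res[[r]] <- data.frame(round = r, n_pairs = rs$n_pairs,
                           shift_prop = rs$shift_proportion,
                           outside_prop = rs$outside_given_shift,
                           confounding_prop = rs$confounding_proportion)
    if (keep_audit) audits[[r]] <- cbind(round = r, rs$audit)
  }
  rounds <- do.call(rbind, res)
  pooled <- c(shift_proportion = mean(rounds$shift_prop),
              outside_given_shift = mean(rounds$outside_prop, na.rm = TRUE),
              confounding_proportion = mean(rounds$confounding_prop))
  probs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  quantiles <- rbind(
    shift_proportion = stats::quantile(rounds$shift_prop, probs, names = FALSE),
    outside_given_shift = if (all(is.na(rounds$outside_prop))) rep(NA_real_, 5) else
      stats::quantile(rounds$outside_prop, probs, names = FALSE, na.rm = TRUE),
    confounding_proportion = stats::quantile(rounds$confounding_prop, probs,
                                             names = FALSE))
  colnames(quantiles) <- paste0(probs * 100, "%")
  out <- structure(list(rounds = rounds, pooled = pooled, quantiles = quantiles,
                        window = space$window, n_rounds = n_rounds,
                        n_pairs = as.integer(n_pairs), seed = seed),
                   class = "ghost_experiment")
  if (keep_audit) out$audit <- do.call(rbind, audits)
  out
}

#' @export
print.ghost_experiment <- function(x, ...) {
  cat(sprintf("Ghost-transfer shift experiment: %d rounds x %d pairs (seed %s)\n",
              x$n_rounds, x$n_pairs, format(x$seed)))
  print(x$window)
  cat(sprintf("  shift proportion:        %.4f\n", x$pooled["shift_proportion"]))
  cat(sprintf("  outside FECA | shift:    %.4f\n", x$pooled["outside_given_shift"]))
  cat(sprintf("  confounding proportion:  %.4f\n", x$pooled["confounding_proportion"]))
  invisible(x)
}

#' @export
summary.ghost_experiment <- function(object, ...) {
  print(object)
  cat("\nAcross-round quantiles:\n")
  print(round(object$quantiles, 4))
  invisible(object)
}

#' @export
as.data.frame.ghost_experiment <- function(x, ...) x$rounds

#' @export
plot.ghost_experiment <- function(x, ...) {
  graphics::hist(x$rounds$shift_prop, breaks = "FD",
                 main = "Per-round shift proportion",
                 xlab = "proportion of shifted pairs", ...)
  graphics::abline(v = x$pooled["shift_proportion"], lty = 2)
  invisible(x)
}

#' Shift proportion stratified by donor clade pair
#'
#' Aggregates the pair-level audit table over unordered donor clade-label
#' pairs: each cell holds the proportion of shifted pairs among all pairs
#' whose two donors carry that pair of labels (the diagonal covers
#' same-clade donor pairs). Cells with no observed pairs are `NA`, not 0.
#'
#' @param x A `ghost_experiment` run with `keep_audit = TRUE`, or a
#'   pair-level audit data.frame with columns `clade_1`, `clade_2`,
#'   `is_shift`.
#' @return Object of class `clade_pair_matrix`: list with `labels`,
#'   `shift_prop` (symmetric matrix), and `n_pairs` (symmetric count
#'   matrix).
#' @export
pair_matrix <- function(x) {
  audit <- if (inherits(x, "ghost_experiment")) {
    if (is.null(x$audit))
      stop_input("experiment has no audit table; rerun with keep_audit = TRUE")
    x$audit
  } else x
  need <- c("clade_1", "clade_2", "is_shift")
  if (!is.data.frame(audit) || !all(need %in% names(audit)))
    stop_input("audit must contain columns clade_1, clade_2, is_shift")
  a <- pmin(audit$clade_1, audit$clade_2)
  b <- pmax(audit$clade_1, audit$clade_2)
  labels <- sort(unique(c(a, b)))
  key <- paste(a, b, sep = "\r")
  n <- tapply(audit$is_shift, key, length)
  s <- tapply(audit$is_shift, key, sum)
  k <- length(labels)
  nm <- matrix(0L, k, k, dimnames = list(labels, labels))
  pm <- matrix(NA_real_, k, k, dimnames = list(labels, labels))
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  for (i in seq_along(n)) {
    la <- parts[[i]][1L]; lb <- parts[[i]][2L]
    nm[la, lb] <- nm[lb, la] <- as.integer(n[i])
    pm[la, lb] <- pm[lb, la] <- s[i] / n[i]
  }
  structure(list(labels = labels, shift_prop = pm, n_pairs = nm),
            class = "clade_pair_matrix")
}

#' @export
print.clade_pair_matrix <- function(x, digits = 4, ...) {
  cat(sprintf("Clade-pair shift matrix (%d clades, %d pairs total)\n",
              length(x$labels), sum(x$n_pairs[upper.tri(x$n_pairs, diag = TRUE)])))
  print(round(x$shift_prop, digits))
  invisible(x)
}

#' @export
as.data.frame.clade_pair_matrix <- function(x, ...) {
  k <- length(x$labels)
  ij <- which(upper.tri(x$n_pairs, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(clade_a = x$labels[ij[, 1L]],
                   clade_b = x$labels[ij[, 2L]],
                   n_pairs = x$n_pairs[ij],
                   shift_prop = x$shift_prop[ij],
                   stringsAsFactors = FALSE)
  df <- df[order(df$clade_a, df$clade_b), ]
  rownames(df) <- NULL
  df
}

#' Sweep the proportion of ghost donors
#'
#' The base simulation assumes the worst case in which every donor is a
#' ghost. Here each pair member is independently declared a ghost with
#' probability `p` (Bernoulli); a ghost donor's observed age is its ghost
#' birth, a sampled donor's observed age is the true transfer age. The same
#' underlying ghost/transfer draws (and the same per-member uniforms for
#' the Bernoulli thresholds) are reused across the whole `p_grid` (common
#' random numbers), so the curve is smooth in `p` for a given seed.
#'
#' @param space A `branch_space`.
#' @param p_grid Numeric vector of ghost proportions in `[0, 1]`.
#' @param n_pairs Number of pairs (shared across grid points).
#' @param seed Master seed (mandatory).
#' @return Object of class `ghost_sweep`: a list with `sweep` (data.frame
#'   `p`, `n_pairs`, `shift_prop`), the `window`, `n_pairs` and `seed`.
#' @export
ghost_fraction_sweep <- function(space, p_grid, n_pairs, seed) {
  stopifnot(inherits(space, "branch_space"))
  p_grid <- as.numeric(p_grid)
  if (!length(p_grid) || anyNA(p_grid) || any(p_grid < 0 | p_grid > 1))
    stop_input("p_grid values must lie in [0, 1]")
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 1L) stop_input("n_pairs must be >= 1")
  if (missing(seed) || is.null(seed)) stop_input("seed is mandatory")
  set.seed(derive_seed(seed, 0L))
  pr <- draw_pairs_vec(space, n_pairs)
  u1 <- stats::runif(n_pairs)
  u2 <- stats::runif(n_pairs)
  shift_prop <- vapply(p_grid, function(p) {
    obs1 <- ifelse(u1 < p, pr$m1$ghost_birth, pr$m1$transfer_age)
    obs2 <- ifelse(u2 < p, pr$m2$ghost_birth, pr$m2$transfer_age)
    cl <- classify_vec(pr$m1$transfer_age, obs1,
                       pr$m2$transfer_age, obs2,
                       space$window$feca_age)
    mean(cl$is_shift)
  }, numeric(1))
  structure(list(sweep = data.frame(p = p_grid, n_pairs = n_pairs,
                                    shift_prop = shift_prop),
                 window = space$window, n_pairs = n_pairs, seed = seed),
            class = "ghost_sweep")
}

#' @export
print.ghost_sweep <- function(x, ...) {
  cat(sprintf("Ghost-proportion sweep (%d pairs per point, seed %s):\n",
              x$n_pairs, format(x$seed)))
  print(x$sweep, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ghost_sweep <- function(x, ...) x$sweep

#' @export
plot.ghost_sweep <- function(x, ...) {
  plot(x$sweep$p, x$sweep$shift_prop, type = "b",
       xlab = "proportion of ghost donors",
       ylab = "proportion of shifted pairs", ...)
  invisible(x)
}

# TSV writers (CLI surface) -------------------------------------------------

#' Write experiment results as TSV
#'
#' `write_round_summary` writes one row per round (`round`, `n_pairs`,
#' `shift_prop`, `outside_prop`, `confounding_prop`); `write_audit` writes
#' the long-format per-transfer log (`round`, `pair_index`, `member`,
#' `branch_id`, `clade_label`, `ghost_birth`, `transfer_age`,
#' `observed_age`); `write_pair_matrix` and `write_sweep` write the
#' long-format clade matrix and the sweep grid.
#'
#' @param x The object to write (`ghost_experiment`, `clade_pair_matrix`,
#'   or `ghost_sweep` as appropriate).
#' @param path Output file path.
#' @param header Optional comment lines (without the leading `#`).
#' @return Invisibly, `path`.
#' @export
write_round_summary <- function(x, path, header = character(0)) {
  stopifnot(inherits(x, "ghost_experiment"))
  write_tsv_commented(x$rounds, path, header)
}

#' @rdname write_round_summary
#' @export
write_audit <- function(x, path, header = character(0)) {
  stopifnot(inherits(x, "ghost_experiment"))
  if (is.null(x$audit))
    stop_input("experiment has no audit table; rerun with keep_audit = TRUE")
  a <- x$audit
  long <- data.frame(
    round = rep(a$round, 2L),
    pair_index = rep(a$pair, 2L),
    member = rep(1:2, each = nrow(a)),
    branch_id = c(a$branch_id_1, a$branch_id_2),
    clade_label = c(a$clade_1, a$clade_2),
    ghost_birth = c(a$ghost_birth_1, a$ghost_birth_2),
    transfer_age = c(a$transfer_age_1, a$transfer_age_2),
    observed_age = c(a$observed_age_1, a$observed_age_2),
    stringsAsFactors = FALSE)
  long <- long[order(long$round, long$pair_index, long$member), ]
  write_tsv_commented(long, path, header)
}

#' @rdname write_round_summary
#' @export
write_pair_matrix <- function(x, path, header = character(0)) {
  stopifnot(inherits(x, "clade_pair_matrix"))
  write_tsv_commented(as.data.frame(x), path, header)
}

#' @rdname write_round_summary
#' @export
write_sweep <- function(x, path, header = character(0)) {
  stopifnot(inherits(x, "ghost_sweep"))
  write_tsv_commented(x$sweep, path, header)
}
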