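mk_pair <- function(g1, t1, g2, t2, obs1 = g1, obs2 = g2) {
  data.frame(branch_id = c("a", "b"), clade_label = c("A", "B"),
             ghost_birth = c(g1, g2), transfer_age = c(t1, t2),
             observed_age = c(obs1, obs2))
}

test_that("classify_pair detects strict order reversals", {
  w <- acceptor_window(2.42, 1.89)
  # consistent ordering: member 1 older on both scales
  cl <- classify_pair(mk_pair(2.3, 2.1, 2.0, 1.95), w)
  expect_equal(cl$true_early, 1L)
  expect_equal(cl$observed_early, 1L)
  expect_false(cl$is_shift)
  expect_false(cl$outside_window)

  # reversal inside the window
  cl <- classify_pair(mk_pair(2.4, 1.90, 2.0, 1.99), w)
  expect_equal(cl$true_early, 2L)
  expect_equal(cl$observed_early, 1L)
  expect_true(cl$is_shift)
  expect_false(cl$outside_window)  # 2.4 < feca

  # reversal whose observed age predates FECA
  cl <- classify_pair(mk_pair(2.50, 1.90, 2.0, 1.99), w)
  expect_true(cl$is_shift)
  expect_true(cl$outside_window)

  # ties on either scale classify as no shift
  expect_false(classify_pair(mk_pair(2.2, 2.0, 2.2, 1.9), w)$is_shift)
  expect_false(classify_pair(mk_pair(2.3, 2.0, 2.1, 2.0), w)$is_shift)
})

test_that("classification is invariant under swapping the pair members", {
  w <- acceptor_window(2.42, 1.89)
  set.seed(8)
  for (i in 1:50) {
    g <- runif(2, 1.9, 3); tau <- runif(2, 1.89, pmin(g, 2.42))
    p <- mk_pair(g[1], tau[1], g[2], tau[2])
    q <- p[2:1, ]
    a <- classify_pair(p, w); b <- classify_pair(q, w)
    expect_equal(a$is_shift, b$is_shift)
    expect_equal(a$outside_window, b$outside_window)
  }
})

test_that("run_round summarises proportions and handles edge sizes", {
  space <- make_fixture_space(sym_fixture())
  r1 <- run_round(space, 1, seed = 1)
  expect_true(r1$shift_proportion %in% c(0, 1))
  expect_error(run_round(space, 0), class = "ghostshift_input_error")

  n <- 1e5
  rr <- run_round(space, n, seed = 2)
  # analytic shift probability for the symmetric fixture is 1/4
  expect_lt(abs(rr$shift_proportion - 0.25), mc_tol(0.25, n, 0, 1))
  # ghost births never exceed FECA here, so no shifted pair leaves the window
  expect_equal(rr$outside_given_shift, 0)
  expect_equal(rr$confounding_proportion, rr$shift_proportion)
})

test_that("confounding = shift x (1 - outside|shift) holds per round", {
  for (s in 1:6) {
    space <- make_fixture_space(rand_fixture(s, n_branches = 4))
    rr <- run_round(space, 5000, seed = s)
    if (is.na(rr$outside_given_shift)) {
      expect_equal(rr$confounding_proportion, 0)
    } else {
      expect_equal(rr$confounding_proportion,
                   rr$shift_proportion * (1 - rr$outside_given_shift),
                   tolerance = 1e-12)
    }
    # an unbiased coin is the worst case for the shift proportion
    expect_lt(rr$shift_proportion, 0.5 + mc_tol(0.5, 5000, 0, 1))
  }
})

test_that("run_experiment is deterministic and pools rounds correctly", {
  space <- make_fixture_space(sym_fixture())
  a <- run_experiment(space, n_rounds = 5, n_pairs = 200, seed = 10)
  b <- run_experiment(space, n_rounds = 5, n_pairs = 200, seed = 10)
  expect_identical(a$rounds, b$rounds)
  expect_equal(a$pooled[["shift_proportion"]], mean(a$rounds$shift_prop))

  ex <- run_experiment(space, n_rounds = 100, n_pairs = 1000, seed = 11)
  expect_lt(abs(ex$pooled[["shift_proportion"]] - 0.25),
            mc_tol(0.25, 100 * 1000, 0, 1))
  expect_equal(dim(ex$quantiles), c(3L, 5L))
  expect_true(all(diff(ex$quantiles["shift_proportion", ]) >= 0))
  expect_error(run_experiment(space, 5, 100), class = "ghostshift_input_error")
})

test_that("pair_matrix aggregates by unordered clade pair", {
  # single clade: the 1x1 matrix equals the overall shift proportion
  space <- make_fixture_space(sym_fixture())
  ex <- run_experiment(space, 4, 500, seed = 12, keep_audit = TRUE)
  pm <- pair_matrix(ex)
  expect_equal(dim(pm$shift_prop), c(1L, 1L))
  expect_equal(pm$shift_prop["S", "S"], ex$pooled[["shift_proportion"]])

  # two clades: cells match the conditional brute-force oracle
  fx <- fixture_spec(2.42, 1.89,
                     data.frame(birth = c(3.0, 2.41), death = c(0, 0),
                                label = c("P", "Q")))
  sp2 <- make_fixture_space(fx)
  n <- 2e5
  ex2 <- run_experiment(sp2, 10, n / 10, seed = 13, keep_audit = TRUE)
  pm2 <- pair_matrix(ex2)
  expect_true(isSymmetric(pm2$shift_prop))
  expect_true(isSymmetric(pm2$n_pairs * 1))
  combos <- list(PP = c(1L, 1L), PQ = c(1L, 2L), QQ = c(2L, 2L))
  cells <- list(PP = c("P", "P"), PQ = c("P", "Q"), QQ = c("Q", "Q"))
  for (k in names(combos)) {
    o <- shift_probability_oracle(fx, branch_pair = combos[[k]],
                                  n_draws = 2e5, seed = 14)
    got <- pm2$shift_prop[cells[[k]][1], cells[[k]][2]]
    n_cell <- pm2$n_pairs[cells[[k]][1], cells[[k]][2]]
    expect_lt(abs(got - o$estimate),
              3 * sqrt(o$se^2 + o$estimate * (1 - o$estimate) / n_cell))
  }
  # long-format export is symmetric by construction (clade_a <= clade_b)
  df <- as.data.frame(pm2)
  expect_equal(nrow(df), 3L)
  expect_true(all(df$clade_a <= df$clade_b))
  expect_equal(sum(df$n_pairs), n)
})

test_that("pair cells with no observations are NA, not zero", {
  audit <- data.frame(clade_1 = c("A", "A"), clade_2 = c("A", "B"),
                      is_shift = c(FALSE, TRUE))
  pm <- pair_matrix(audit)
  expect_true(is.na(pm$shift_prop["B", "B"]))
  expect_equal(pm$n_pairs["B", "B"], 0L)
  expect_equal(pm$shift_prop["A", "B"], 1)
})

test_that("ghost_fraction_sweep: p=0 gives exactly zero shifts", {
  for (s in c(20, 21)) {
    space <- make_fixture_space(rand_fixture(s, n_branches = 3))
    sw <- ghost_fraction_sweep(space, c(0, 0.3, 1), n_pairs = 5000, seed = s)
    expect_equal(sw$sweep$shift_prop[1], 0)
    expect_error(ghost_fraction_sweep(space, c(0, 1.5), 100, seed = 1),
                 class = "ghostshift_input_error")
  }
})

test_that("sweep at p=1 agrees in distribution with the base simulation", {
  space <- make_fixture_space(sym_fixture())
  n <- 1e5
  sw <- ghost_fraction_sweep(space, 1, n_pairs = n, seed = 30)
  rr <- run_round(space, n, seed = 31)
  ht <- stats::prop.test(c(sw$sweep$shift_prop * n, rr$shift_proportion * n),
                         c(n, n))
  expect_gt(ht$p.value, 0.001)
})

test_that("sweep at intermediate p matches the mixture-decomposition oracle", {
  fx <- sym_fixture()
  space <- make_fixture_space(fx)
  p <- 0.5
  n <- 1e5
  sw <- ghost_fraction_sweep(space, p, n_pairs = n, seed = 33)
  # enumerate the four ghost/extant member combinations, brute-force each
  # conditional shift probability, and mix with the Bernoulli weights
  parts <- list(list(g = c(1, 1), w = p^2),
                list(g = c(1, 0), w = p * (1 - p)),
                list(g = c(0, 1), w = (1 - p) * p),
                list(g = c(0, 0), w = (1 - p)^2))
  mix <- 0; var_mix <- 0
  for (pt in parts) {
    o <- shift_probability_oracle(fx, p_ghost = pt$g, n_draws = 1e5, seed = 34)
    mix <- mix + pt$w * o$estimate
    var_mix <- var_mix + (pt$w * o$se)^2
  }
  se_sw <- sqrt(sw$sweep$shift_prop * (1 - sw$sweep$shift_prop) / n)
  expect_lt(abs(sw$sweep$shift_prop - mix), 3 * sqrt(var_mix + se_sw^2))
})

test_that("sweep reuses draws across the grid (common random numbers)", {
  space <- make_fixture_space(sym_fixture())
  sw1 <- ghost_fraction_sweep(space, c(0, 0.5, 1), n_pairs = 2000, seed = 40)
  sw2 <- ghost_fraction_sweep(space, c(0.5), n_pairs = 2000, seed = 40)
  expect_equal(sw1$sweep$shift_prop[2], sw2$sweep$shift_prop[1])
})
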