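test_that("activity decomposition matches hand-computed |K| and |K e| on a toy filter", {
  d <- orthonormal_dictionary(2, 4, seed = 1)
  obs <- rbind(0.8 * d$elements[1, ] + 0.1 * d$elements[2, ],
               0.5 * d$elements[1, ])
  sc <- as.matrix(obs)
  traj <- run_icpa(sc, d, p0_diag = 0.5, keep_history = TRUE)
  act <- decompose_activity(traj, pulse_steps = c(1L, 2L), lead_steps = 1L)
  for (t in 1:2) {
    K <- traj$history[[t]]$K
    e <- traj$history[[t]]$e
    for (h in 1:2) for (i in 1:4) {
      expect_equal(act$k_activity[h, i, t], abs(K[h, i]), tolerance = 1e-12)
      expect_equal(act$d_activity[h, i, t], abs(K[h, i] * e[i]),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(act$k_activity >= 0) && all(act$d_activity >= 0))

  # a perfectly predicted step has zero parameter-error activity but
  # nonzero uncertainty activity
  st <- init_state(2, c0 = c(1, 0), p0_diag = 1)
  st <- update_state(st, 0.9 * d$elements[1, ], d)
  expect_equal(max(abs(st$diagnostics$e)), 0, tolerance = 1e-12)
  expect_gt(max(abs(st$diagnostics$K)), 0)

  traj_bare <- run_icpa(sc, d)
  expect_error(decompose_activity(traj_bare), "lacks diagnostics")
})

test_that("response metrics normalize the last pulse by the first", {
  mk_act <- function(series) {
    # one K unit, one D unit, both following `series` over 5 steps
    a <- array(rep(series, each = 1), c(1, 1, length(series)))
    structure(list(k_activity = a, d_activity = a,
                   pulse_steps = c(2L, 5L), lead_steps = 1L,
                   n = 1L, f = 1L),
              class = "circuit_activity")
  }
  flat <- response_metrics(mk_act(rep(2, 5)))
  expect_equal(flat$normalized_last, rep(1, 2))
  halved <- response_metrics(mk_act(c(1, 2, 2, 2, 1)))
  expect_equal(halved$normalized_last, rep(0.5, 2))
  expect_equal(halved$spontaneous, rep(1, 2))

  dead <- mk_act(c(1, 0, 0, 0, 0))
  res <- response_metrics(dead)
  expect_true(all(res$excluded))
  expect_identical(attr(res, "n_excluded"), 2L)

  no_lead <- mk_act(rep(1, 5)); no_lead$lead_steps <- integer()
  expect_error(response_metrics(no_lead), "no spontaneous window")
  one_pulse <- mk_act(rep(1, 5)); one_pulse$pulse_steps <- 2L
  expect_error(response_metrics(one_pulse), "at least two pulses")
})

test_that("spearman_with_ci matches the rank-then-Pearson oracle and Fisher interval", {
  expect_equal(spearman_with_ci(1:10, 2 * (1:10) + 3)$rho, 1)
  expect_equal(spearman_with_ci(1:10, -(1:10))$rho, -1)

  x <- c(3.1, 0.2, 5.5, 2.2, 4.4, 1.0)
  y <- c(0.5, 1.2, 0.3, 2.0, 0.9, 1.1)
  res <- spearman_with_ci(x, y)
  expect_equal(res$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  z <- atanh(res$rho)
  hw <- qnorm(0.975) / sqrt(6 - 3)
  expect_equal(res$ci_low, tanh(z - hw), tolerance = 1e-12)
  expect_equal(res$ci_high, tanh(z + hw), tolerance = 1e-12)
  expect_error(spearman_with_ci(rep(1, 6), y), "undefined correlation")
  expect_error(spearman_with_ci(1:3, 1:3), "at least 4")
})

test_that("adaptation fits recover exponential decay parameters", {
  k <- 1:9
  exact <- 1 * exp(-k / 2) + 0.1
  fit <- fit_adaptation(exact)
  expect_equal(fit$amplitude, 1, tolerance = 1e-6)
  expect_equal(fit$tau, 2, tolerance = 1e-6)
  expect_equal(fit$offset, 0.1, tolerance = 1e-6)
  expect_lt(fit$fit_error, 1e-12)

  flat <- fit_adaptation(rep(0.7, 6))
  expect_lt(abs(flat$amplitude), 1e-6)
  expect_equal(flat$offset + flat$amplitude * mean(exp(-(1:6) / flat$tau)),
               0.7, tolerance = 1e-3)

  # noisy recovery across seeds: median relative parameter error < 10%
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- exact + rnorm(9, 0, 0.01)
    f <- tryCatch(fit_adaptation(noisy), error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    max(abs(c(f$amplitude - 1, f$tau - 2, f$offset - 0.1) / c(1, 2, 0.1)))
  }, numeric(1))
  expect_lt(median(errs, na.rm = TRUE), 0.10)

  expect_error(fit_adaptation(c(1, 2)), "at least 3")
})

test_that("a reduced click-train simulation shows the two predicted unit classes", {
  res <- click_train_experiment(seed = 5, f = 30L, n = 40L, n_pulses = 5L,
                                gap = 10L, lead_silence = 10L)
  units <- res$units[!res$units$excluded, ]
  k_units <- units[units$population == "K", ]
  d_units <- units[units$population == "D", ]
  # uncertainty units keep markedly higher spontaneous activity
  expect_gt(median(k_units$spontaneous), 10 * median(d_units$spontaneous))
  # parameter-error units adapt more strongly
  expect_lt(mean(d_units$normalized_last), mean(k_units$normalized_last))
  # the estimation error decays over the train and the element is found
  expect_lt(res$e_norm_pulses[5], res$e_norm_pulses[1])
  expect_identical(res$identified_index, 1L)
  # spontaneous correlation exceeds the evoked correlation
  expect_gt(res$rho_spontaneous$rho, res$rho_evoked$rho)
})
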