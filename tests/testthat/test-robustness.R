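test_that("perturb_params applies theta * (1 + mu * eps) to targets only", {
  b <- make_benchmark()
  th <- nlgrn:::params_to_theta(b$params, b$net)
  expect_equal(perturb_params(b$params, b$net, 0, rnorm(length(th))), th)
  net1 <- grn_network("G1")
  p1 <- grn_params(NULL, NULL, c(G1 = 0.5), net1)
  expect_equal(perturb_params(p1, net1, 0.4, 1), 0.7)
  # degradation_only leaves couplings untouched
  pt <- perturb_params(b$params, b$net, 0.4, rep(1, length(th)),
                       targets = "degradation_only")
  expect_equal(pt[1:7], th[1:7])
  expect_equal(pt[8:12], th[8:12] * 1.4)
  # empirical sd of kbar/k over many draws is mu
  set.seed(14)
  draws <- vapply(rnorm(1e5), function(e)
    perturb_params(p1, net1, 0.4, e) / 0.5, numeric(1))
  expect_lt(abs(sd(draws) - 0.4) / 0.4, 0.02)
})

test_that("robustness statistics follow their definitions", {
  ds <- make_decay_ds()
  net <- grn_network("G1")
  p <- grn_params(NULL, NULL, c(G1 = 0.5), net)
  # mu = 0: all perturbed simulations coincide with the baseline
  r0 <- robustness(net, p, ds, robustness_config(mu = 0, n_perturb = 50))
  expect_identical(r0$RA, 0)
  expect_identical(r0$RSTD, 0)
  expect_identical(r0$n_failed, 0L)
  # RA / RSTD are the mean and sample sd of the E vector, hence invariant
  # to the order of the draws
  r <- robustness(net, p, ds, robustness_config(mu = 0.1, n_perturb = 200,
                                                seed = 2))
  expect_equal(r$RA, mean(r$E, na.rm = TRUE))
  expect_equal(r$RSTD, sd(r$E[is.finite(r$E)]))
  set.seed(1)
  perm <- sample(length(r$E))
  expect_equal(mean(r$E[perm], na.rm = TRUE), r$RA)
  # uniform noise option stays within the +/- mu band
  ru <- robustness(net, p, ds, robustness_config(mu = 0.1, n_perturb = 100,
                                                 noise = "uniform", seed = 3))
  expect_equal(ru$n_failed, 0L)
  expect_lte(max(ru$E), max(r$E, na.rm = TRUE))
})

test_that("RA grows linearly in mu on the decay model", {
  ds <- make_decay_ds()
  net <- grn_network("G1")
  p <- grn_params(NULL, NULL, c(G1 = 0.5), net)
  grid <- ds$times
  # analytic slope: E(kbar) ~ |kbar - k| * sqrt(sum (t e^{-kt})^2), so
  # dRA/dmu at 0 is k * E|eps| * that norm
  slope <- 0.5 * sqrt(2 / pi) * sqrt(sum((grid * exp(-0.5 * grid))^2))
  for (mu in c(0.005, 0.01)) {
    r <- robustness(net, p, ds,
                    robustness_config(mu = mu, n_perturb = 4000, seed = 5,
                                      targets = "degradation_only"))
    expect_lt(abs(r$RA / mu - slope) / slope, 0.10)
  }
})

test_that("score_removal zeroes coefficients without refitting", {
  b <- make_benchmark()
  # add a spurious zero-coefficient NLT edge
  net2 <- b$net
  net2$nlt_edges <- rbind(net2$nlt_edges,
                          data.frame(first = "G1", second = "G3",
                                     target = "G2", rank = NA_real_,
                                     p_value = NA_real_))
  rcfg <- robustness_config(mu = 0.1, n_perturb = 50, seed = 6)
  base_tr <- simulate_trajectory(b$params, net2, b$x0, b$ds$times)
  base_se <- simulation_error(base_tr, b$ds)
  step <- score_removal(net2, b$params, b$ds,
                        nlt_edges = data.frame(first = "G1", second = "G3",
                                               target = "G2"),
                        rcfg = rcfg)
  expect_identical(step$SE, base_se)  # zero coefficient: exactly unchanged
  # removing a live edge changes the error
  step2 <- score_removal(b$net, b$params, b$ds,
                         gene_edges = data.frame(source = "G2",
                                                 target = "G4"),
                         rcfg = rcfg)
  expect_gt(step2$SE, base_se)
  expect_error(score_removal(b$net, b$params, b$ds,
                             gene_edges = data.frame(source = "G5",
                                                     target = "G1"),
                             rcfg = rcfg),
               "not present")
  # removing every edge leaves the degradation-only model
  all_removed <- score_removal(b$net, b$params, b$ds,
                               gene_edges = b$net$gene_edges,
                               nlt_edges = b$net$nlt_edges, rcfg = rcfg)
  deg_par <- grn_params(NULL, NULL, b$params$k)
  deg_net <- grn_network(b$net$genes)
  deg_tr <- simulate_trajectory(deg_par, deg_net, b$x0, b$ds$times)
  expect_equal(all_removed$SE, simulation_error(deg_tr, b$ds),
               tolerance = 1e-10)
})

test_that("greedy_prune produces a nested, well-formed trace", {
  b <- make_benchmark()
  fit <- structure(list(params = b$params, error = 0, seed = 1,
                        generations_run = 0L, normalize = "none"),
                   class = "fit_result")
  rcfg <- robustness_config(mu = 0.1, n_perturb = 100, seed = 7)
  trace <- greedy_prune(b$net, fit, b$ds, rcfg, screen_n = 30)
  df <- as.data.frame(trace)
  expect_equal(df$Model[1], "OES")
  expect_equal(df$RR[1], "N/A")
  if (length(trace) > 1)
    expect_equal(df$Model[-1], paste0("DEL", seq_len(length(trace) - 1)))
  # replaying the trace reproduces the final network edge counts
  final <- apply_trace(b$net, trace)
  pruned <- attr(trace, "network")
  expect_equal(nrow(final$gene_edges), nrow(pruned$gene_edges))
  expect_equal(nrow(final$nlt_edges), nrow(pruned$nlt_edges))
  # trace CSV layout
  path <- withr::local_tempfile()
  write_trace(trace, path)
  expect_equal(names(utils::read.csv(path)),
               c("Model", "RR", "SE", "RA", "RSTD"))
})
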