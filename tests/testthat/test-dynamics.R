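test_that("the model right-hand side matches hand calculations and a dense oracle", {
  net1 <- grn_network("G1")
  p1 <- grn_params(NULL, NULL, c(G1 = 0.5), net1)
  expect_equal(grn_rhs(p1, net1, 2), -1)
  g3 <- paste0("G", 1:3)
  net3 <- grn_network(g3,
                      gene_edges = data.frame(source = "G1", target = "G2"),
                      nlt_edges = data.frame(first = "G1", second = "G2",
                                             target = "G3"))
  p3 <- grn_params(data.frame(source = "G1", target = "G2", value = 0),
                   data.frame(first = "G1", second = "G2", target = "G3",
                              value = 1),
                   c(G1 = 1e-9, G2 = 1e-9, G3 = 1e-9), net3)
  f <- grn_rhs(p3, net3, c(2, 3, 0))
  expect_equal(f[3], 6, tolerance = 1e-9)

  # random sparse 4-gene system against a naive dense-matrix oracle
  set.seed(12)
  g4 <- paste0("G", 1:4)
  spec <- synthetic_spec(m = 4, m1 = 5, n1 = 3, seed = 13)
  tru <- generate_network(spec)
  x <- runif(4, 0.2, 2)
  # dense oracle: full alpha matrix, full beta array
  A <- matrix(0, 4, 4)
  for (r in seq_len(nrow(tru$params$alpha)))
    A[match(tru$params$alpha$target[r], tru$network$genes),
      match(tru$params$alpha$source[r], tru$network$genes)] <-
      tru$params$alpha$value[r]
  B <- array(0, c(4, 4, 4))
  for (r in seq_len(nrow(tru$params$beta)))
    B[match(tru$params$beta$target[r], tru$network$genes),
      match(tru$params$beta$first[r], tru$network$genes),
      match(tru$params$beta$second[r], tru$network$genes)] <-
      tru$params$beta$value[r]
  ref <- numeric(4)
  for (i in 1:4) {
    ref[i] <- -tru$params$k[i] * x[i] + sum(A[i, ] * x)
    for (j in 1:4) for (k in 1:4) ref[i] <- ref[i] + B[i, j, k] * x[j] * x[k]
  }
  expect_equal(grn_rhs(tru$params, tru$network, x), ref, tolerance = 1e-12)
})

test_that("simulate_trajectory matches closed forms", {
  net <- grn_network("G1")
  p <- grn_params(NULL, NULL, c(G1 = 0.5), net)
  tr <- simulate_trajectory(p, net, 1, c(0, 2))
  expect_equal(tr$values[1, 2], exp(-1), tolerance = 1e-4)
  expect_equal(tr$values[1, 1], 1)  # initial condition reported at t1
  expect_equal(tr$status, "ok")

  # linear-only 3-gene system against the matrix exponential
  g3 <- paste0("G", 1:3)
  net3 <- grn_network(g3, data.frame(source = c("G1", "G2"),
                                     target = c("G2", "G3")))
  p3 <- grn_params(data.frame(source = c("G1", "G2"),
                              target = c("G2", "G3"),
                              value = c(0.05, -0.03)),
                   NULL, setNames(c(0.1, 0.2, 0.3), g3), net3)
  A <- matrix(0, 3, 3)
  A[2, 1] <- 0.05; A[3, 2] <- -0.03
  diag(A) <- -c(0.1, 0.2, 0.3)
  x0 <- c(1, 0.5, 2)
  grid <- paper_time_grid()
  tr3 <- simulate_trajectory(p3, net3, x0, grid)
  for (j in c(2, 10, 20, 30)) {
    ref <- as.numeric(Matrix::expm(A * grid[j]) %*% x0)
    expect_equal(unname(tr3$values[, j]), ref, tolerance = 1e-6)
  }

  # the origin is a fixed point
  tr0 <- simulate_trajectory(p3, net3, c(0, 0, 0), grid)
  expect_true(all(tr0$values == 0))
})

test_that("solver tolerances are converged on the benchmark world", {
  b <- make_benchmark()
  t1 <- simulate_trajectory(b$params, b$net, b$x0, b$ds$times)
  t2 <- simulate_trajectory(b$params, b$net, b$x0, b$ds$times,
                            rtol = 5e-7, atol = 5e-9)
  expect_lt(max(abs(t1$values - t2$values)), 1e-5)
})

test_that("unstable systems report divergence instead of erroring", {
  g2 <- c("G1", "G2")
  net <- grn_network(g2,
                     gene_edges = data.frame(source = "G1", target = "G2"),
                     nlt_edges = data.frame(first = "G1", second = "G2",
                                            target = "G1"))
  p <- grn_params(data.frame(source = "G1", target = "G2", value = 1),
                  data.frame(first = "G1", second = "G2", target = "G1",
                             value = 2),
                  c(G1 = 0.01, G2 = 0.01), net)
  tr <- simulate_trajectory(p, net, c(1, 1), c(0, 50, 100))
  expect_equal(tr$status, "diverged")
  expect_true(is.infinite(simulation_error(tr, gene_dataset(
    g2, c(0, 50, 100), matrix(1, 2, 3)))))
})

test_that("simulation_error is the root total sum of squares", {
  grid <- c(0, 1)
  ds <- gene_dataset(c("a", "b"), grid, rbind(c(1, 2), c(3, 4)))
  traj <- structure(list(times = grid, values = ds$values, status = "ok"),
                    class = "trajectory")
  rownames(traj$values) <- ds$genes
  expect_equal(simulation_error(traj, ds), 0)
  traj2 <- traj
  traj2$values[1, 2] <- traj2$values[1, 2] + 0.5
  expect_equal(simulation_error(traj2, ds), 0.5)
  traj3 <- traj
  traj3$values <- traj3$values + diag(c(1, 1))
  expect_equal(simulation_error(traj3, ds), sqrt(2))
  # invariant under a consistent permutation of the genes
  dsp <- gene_dataset(c("b", "a"), grid, ds$values[2:1, ])
  trajp <- traj3
  trajp$values <- trajp$values[2:1, ]
  expect_equal(simulation_error(trajp, dsp), simulation_error(traj3, ds))
})

test_that("trajectories export through the expression dialect", {
  b <- make_benchmark()
  tr <- simulate_trajectory(b$params, b$net, b$x0, b$ds$times)
  path <- withr::local_tempfile()
  write_expression(trajectory_dataset(tr), path)
  back <- read_expression(path)
  expect_equal(back$values, tr$values, tolerance = 1e-12)
})
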