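# The non-linear ODE model and its simulation-error statistic.
# dx_i/dt = sum_{j->i} alpha_ij x_j + sum_{(j,k)->i} beta_ijk x_j x_k - k_i x_i

# 0-based sparse structure handed to the C++ integrator. Theta layout:
# [alpha (gene-edge order), beta (NLT-edge order), k (gene order)].
model_structure <- function(net) {
  stopifnot(inherits(net, "grn_network"))
  genes <- net$genes
  list(m = length(genes),
       a_src = match(net$gene_edges$source, genes) - 1L,
       a_dst = match(net$gene_edges$target, genes) - 1L,
       b_j = match(net$nlt_edges$first, genes) - 1L,
       b_k = match(net$nlt_edges$second, genes) - 1L,
       b_i = match(net$nlt_edges$target, genes) - 1L)
}

# flatten grn_params into the theta layout of `model_structure(net)`
params_to_theta <- function(params, net) {
  key <- function(...) paste(..., sep = "\r")
  ge <- net$gene_edges; ne <- net$nlt_edges
  a <- rep(0, nrow(ge)); b <- rep(0, nrow(ne))
  if (nrow(params$alpha)) {
    idx <- match(key(params$alpha$source, params$alpha$target),
                 key(ge$source, ge$target))
    if (any(is.na(idx))) stop("alpha entry outside the network support")
    a[idx] <- params$alpha$value
  }
  if (nrow(params$beta)) {
    idx <- match(key(params$beta$first, params$beta$second,
                     params$beta$target),
                 key(ne$first, ne$second, ne$target))
    if (any(is.na(idx))) stop("beta entry outside the network support")
    b[idx] <- params$beta$value
  }
  c(a, b, unname(params$k[net$genes]))
}

theta_to_params <- function(theta, net, k_floor = 1e-9) {
  ge <- net$gene_edges; ne <- net$nlt_edges
  m <- length(net$genes)
  na <- nrow(ge); nb <- nrow(ne)
  stopifnot(length(theta) == na + nb + m)
  k <- theta[na + nb + seq_len(m)]
  if (any(k <= 0)) {
    warning("degradation rate(s) at or below 0 nudged to ", k_floor)
    k[k <= 0] <- k_floor
  }
  grn_params(
    alpha = if (na) data.frame(source = ge$source, target = ge$target,
                               value = theta[seq_len(na)]),
    beta = if (nb) data.frame(first = ne$first, second = ne$second,
                              target = ne$target,
                              value = theta[na + seq_len(nb)]),
    k = setNames(k, net$genes), net = net)
}

#' Model right-hand side (reference implementation)
#'
#' Derivative of the expression state under the sparse non-linear model.
#' Used for documentation and cross-checks; simulation uses the compiled
#' integrator.
#'
#' @param params a [grn_params()].
#' @param net the companion [grn_network()].
#' @param x state vector (length m, ordered as `net$genes`).
#' @return derivative vector of length m.
#' @export
grn_rhs <- function(params, net, x) {
  genes <- net$genes
  stopifnot(length(x) == length(genes))
  f <- -unname(params$k[genes]) * x
  a <- params$alpha
  for (r in seq_len(nrow(a))) {
    i <- match(a$target[r], genes); j <- match(a$source[r], genes)
    f[i] <- f[i] + a$value[r] * x[j]
  }
  b <- params$beta
  for (r in seq_len(nrow(b))) {
    i <- match(b$target[r], genes)
    j <- match(b$first[r], genes); k <- match(b$second[r], genes)
    f[i] <- f[i] + b$value[r] * x[j] * x[k]
  }
  f
}

#' Simulate a model trajectory on a time grid
#'
#' Adaptive Dormand-Prince RK45 integration of the model, reported at the
#' grid times; the first grid point carries the initial condition. States
#' are never clipped to non-negative values. A state exceeding the
#' divergence bound yields status `"diverged"`; step-size underflow yields
#' `"solver_failure"` — neither raises an exception, so robustness sweeps
#' over unstable parameter sets terminate cleanly.
#'
#' @param params a [grn_params()].
#' @param net companion [grn_network()].
#' @param x0 initial state (length m); for fitting, the observed
#'   expression at the first time point.
#' @param times observation grid (hours), see [as_time_grid()].
#' @param rtol,atol solver tolerances.
#' @param div_bound divergence bound on `|state|`; default
#'   `1e6 * max(|x0|, 1)`. Pass `1e6 * max(data)` when fitting.
#' @param time_scale multiplies the grid (experimentation hook; default 1).
#' @return object of class `trajectory`: `times`, `values` (m x M),
#'   `status` one of `"ok"`, `"diverged"`, `"solver_failure"`.
#' @export
simulate_trajectory <- function(params, net, x0, times, rtol = 1e-6,
                                atol = 1e-8, div_bound = NULL,
                                time_scale = 1) {
  times <- as_time_grid(times) * time_scale
  m <- length(net$genes)
  if (length(x0) != m) stop("x0 must have length ", m)
  if (any(!is.finite(x0))) stop("x0 must be finite")
  if (is.null(div_bound)) div_bound <- 1e6 * max(abs(x0), 1)
  st <- model_structure(net)
  theta <- params_to_theta(params, net)
  res <- sim_cpp(st, theta, as.numeric(x0), times, rtol, atol, div_bound)
  status <- c("ok", "diverged", "solver_failure")[res$status + 1L]
  values <- res$values
  dimnames(values) <- list(net$genes, format(times, trim = TRUE))
  structure(list(times = times, values = values, status = status),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", nrow(x$values), " genes x ", length(x$times),
      " time points, status: ", x$status, "\n", sep = "")
  invisible(x)
}

#' Convert a trajectory to a dataset for export
#'
#' Reuses the expression TSV dialect for plotting/diffing. Negative
#' simulated values (the model has no positivity guarantee) are kept, so
#' the result bypasses the dataset non-negativity check.
#'
#' @param traj a `trajectory`.
#' @return a `gene_dataset`-shaped list accepted by [write_expression()].
#' @export
trajectory_dataset <- function(traj) {
  structure(list(genes = rownames(traj$values), times = traj$times,
                 values = traj$values), class = "gene_dataset")
}

#' Simulation error between a trajectory and observed data
#'
#' Square root of the total (unnormalized) sum of squared deviations over
#' all genes and time points. A diverged or failed trajectory yields `Inf`
#' with attribute `failed = TRUE`.
#'
#' @param traj a `trajectory`.
#' @param ds a [gene_dataset()] sharing grid and genes.
#' @return non-negative scalar `E`.
#' @export
simulation_error <- function(traj, ds) {
  if (traj$status != "ok")
    return(structure(Inf, failed = TRUE))
  if (!isTRUE(all.equal(as.numeric(traj$times), as.numeric(ds$times))))
    stop("trajectory and dataset grids differ")
  v <- traj$values
  d <- ds$values
  if (!identical(rownames(v), ds$genes)) {
    idx <- match(ds$genes, rownames(v))
    if (any(is.na(idx))) stop("trajectory and dataset gene sets differ")
    v <- v[idx, , drop = FALSE]
  }
  sqrt(sum((d - v)^2))
}
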