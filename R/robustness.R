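# Perturbation-robustness statistics and the greedy edge-deletion
# (network reduction) procedure.

#' Robustness-analysis configuration
#'
#' Each targeted parameter theta is multiplied by `(1 + mu * eps)` with
#' independent draws of `eps` (standard Gaussian by default, or uniform on
#' [-1, 1]). The published protocol uses `mu = 0.4` and `N = 5000`
#' perturbation sets. Perturbed values are not clipped; unstable parameter
#' sets are excluded via divergence detection and counted.
#'
#' @param mu perturbation magnitude (>= 0).
#' @param n_perturb number of perturbed parameter sets N.
#' @param noise `"normal"` (standard Gaussian) or `"uniform"` (on [-1, 1]).
#' @param targets `"all_parameters"` perturbs alpha, beta and k;
#'   `"degradation_only"` perturbs only the k_i.
#' @param seed RNG seed for the perturbation draws.
#' @return list of class `robustness_config`.
#' @export
robustness_config <- function(mu = 0.4, n_perturb = 5000,
                              noise = c("normal", "uniform"),
                              targets = c("all_parameters",
                                          "degradation_only"),
                              seed = 1) {
  noise <- match.arg(noise)
  targets <- match.arg(targets)
  if (mu < 0) stop("mu must be >= 0")
  if (n_perturb < 1) stop("n_perturb must be >= 1")
  structure(list(mu = mu, n_perturb = n_perturb, noise = noise,
                 targets = targets, seed = seed),
            class = "robustness_config")
}

target_mask <- function(net, targets) {
  na <- nrow(net$gene_edges); nb <- nrow(net$nlt_edges)
  m <- length(net$genes)
  if (targets == "degradation_only")
    c(rep(FALSE, na + nb), rep(TRUE, m))
  else rep(TRUE, na + nb + m)
}

#' Multiplicatively perturb model parameters
#'
#' Applies `theta -> theta * (1 + mu * eps)` to every targeted parameter,
#' with the supplied draws; untargeted parameters pass through. Values are
#' not clipped: a perturbed degradation rate may become non-positive, in
#' which case downstream divergence handling applies (the returned object
#' is a raw theta vector, not a validated `grn_params`).
#'
#' @param params a [grn_params()].
#' @param net companion [grn_network()].
#' @param mu perturbation magnitude.
#' @param eps numeric vector of draws, one per parameter (recycled if
#'   length 1).
#' @param targets see [robustness_config()].
#' @return perturbed theta vector in the layout of the network structure.
#' @export
perturb_params <- function(params, net, mu, eps,
                           targets = "all_parameters") {
  theta <- params_to_theta(params, net)
  mask <- target_mask(net, targets)
  if (length(eps) == 1) eps <- rep(eps, length(theta))
  stopifnot(length(eps) == length(theta))
  theta[mask] <- theta[mask] * (1 + mu * eps[mask])
  theta
}

#' Perturbation-robustness report
#'
#' Simulates the unperturbed model once, then draws `N` perturbed
#' parameter sets, simulates each, and measures the trajectory
#' displacement `E^(k)` (root total squared deviation) of every perturbed
#' simulation from the unperturbed simulation — not from the data. `RA` is
#' the mean and `RSTD` the sample standard deviation (divisor N-1) over
#' the successful perturbations; failures are excluded and counted.
#'
#' @param net a [grn_network()].
#' @param params fitted [grn_params()].
#' @param ds dataset supplying the grid and the initial condition (pass it
#'   on the same scale the parameters were fitted on; see `normalize`).
#' @param cfg a [robustness_config()].
#' @param normalize transform applied to `ds` first (default `"none"`).
#' @return object of class `robustness_report`: `RA`, `RSTD`, `E`
#'   (per-perturbation distances, `NA` for failures), `n_failed`.
#' @export
robustness <- function(net, params, ds, cfg = robustness_config(),
                       normalize = "none") {
  ds <- normalize_dataset(ds, normalize)
  x0 <- ds$values[, 1]
  bound <- 1e6 * max(abs(ds$values), 1)
  base <- simulate_trajectory(params, net, x0, ds$times, div_bound = bound)
  if (base$status != "ok")
    stop("baseline simulation failed with status: ", base$status)
  theta <- params_to_theta(params, net)
  n_par <- length(theta)
  mask <- target_mask(net, cfg$targets)
  set.seed(as.integer(cfg$seed %% .Machine$integer.max))
  N <- cfg$n_perturb
  eps <- if (cfg$noise == "normal") rnorm(N * n_par) else
    runif(N * n_par, -1, 1)
  eps <- matrix(eps, N, n_par)
  eps[, !mask] <- 0
  thetas <- matrix(theta, N, n_par, byrow = TRUE) * (1 + cfg$mu * eps)
  st <- model_structure(net)
  E <- eval_population_cpp(thetas, st, base$values, x0, ds$times,
                           1e-6, 1e-8, bound)
  failed <- !is.finite(E)
  Eok <- E[!failed]
  E[failed] <- NA_real_
  structure(list(RA = mean(Eok), RSTD = if (length(Eok) > 1) sd(Eok) else 0,
                 E = E, n_failed = sum(failed)),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("<robustness_report> RA = ", format(x$RA, digits = 6), ", RSTD = ",
      format(x$RSTD, digits = 6), ", failed ", x$n_failed, "/",
      length(x$E), "\n", sep = "")
  invisible(x)
}

#' Remove edges from a network
#'
#' @param net a [grn_network()].
#' @param gene_edges data.frame `source`, `target` rows to drop (or NULL).
#' @param nlt_edges data.frame `first`, `second`, `target` rows to drop.
#' @return the reduced [grn_network()]; errors if an edge is absent.
#' @export
remove_edges <- function(net, gene_edges = NULL, nlt_edges = NULL) {
  key <- function(...) paste(..., sep = "\r")
  ge <- net$gene_edges; ne <- net$nlt_edges
  if (!is.null(gene_edges) && nrow(gene_edges)) {
    idx <- match(key(gene_edges$source, gene_edges$target),
                 key(ge$source, ge$target))
    if (any(is.na(idx)))
      stop("gene edge not present: ",
           paste(gene_edges$source[is.na(idx)], "->",
                 gene_edges$target[is.na(idx)], collapse = "; "))
    ge <- ge[-idx, , drop = FALSE]
  }
  if (!is.null(nlt_edges) && nrow(nlt_edges)) {
    idx <- match(key(nlt_edges$first, nlt_edges$second, nlt_edges$target),
                 key(ne$first, ne$second, ne$target))
    if (any(is.na(idx)))
      stop("NLT edge not present: ",
           paste(nlt_edges$first[is.na(idx)], ":",
                 nlt_edges$second[is.na(idx)], " -> ",
                 nlt_edges$target[is.na(idx)], collapse = "; "))
    ne <- ne[-idx, , drop = FALSE]
  }
  # a pruned network may transiently violate n1 <= m1; rebuild leniently
  out <- net
  out$gene_edges <- ge
  out$nlt_edges <- ne
  out
}

# drop the parameter rows of removed edges (used when the network itself
# shrinks, so the support invariant keeps holding)
drop_removed <- function(params, gene_edges = NULL, nlt_edges = NULL) {
  key <- function(...) paste(..., sep = "\r")
  if (!is.null(gene_edges) && nrow(gene_edges) && nrow(params$alpha)) {
    hit <- key(params$alpha$source, params$alpha$target) %in%
      key(gene_edges$source, gene_edges$target)
    params$alpha <- params$alpha[!hit, , drop = FALSE]
  }
  if (!is.null(nlt_edges) && nrow(nlt_edges) && nrow(params$beta)) {
    hit <- key(params$beta$first, params$beta$second, params$beta$target) %in%
      key(nlt_edges$first, nlt_edges$second, nlt_edges$target)
    params$beta <- params$beta[!hit, , drop = FALSE]
  }
  params
}

# zero the coefficients of removed edges (no refit by default)
zero_removed <- function(params, gene_edges = NULL, nlt_edges = NULL) {
  key <- function(...) paste(..., sep = "\r")
  if (!is.null(gene_edges) && nrow(gene_edges) && nrow(params$alpha)) {
    hit <- key(params$alpha$source, params$alpha$target) %in%
      key(gene_edges$source, gene_edges$target)
    params$alpha$value[hit] <- 0
  }
  if (!is.null(nlt_edges) && nrow(nlt_edges) && nrow(params$beta)) {
    hit <- key(params$beta$first, params$beta$second, params$beta$target) %in%
      key(nlt_edges$first, nlt_edges$second, nlt_edges$target)
    params$beta$value[hit] <- 0
  }
  params
}

rr_label <- function(gene_edges = NULL, nlt_edges = NULL) {
  lab <- c(
    if (!is.null(nlt_edges) && nrow(nlt_edges))
      paste0(nlt_edges$first, ":", nlt_edges$second, " -> ",
             nlt_edges$target),
    if (!is.null(gene_edges) && nrow(gene_edges))
      paste0(gene_edges$source, " -> ", gene_edges$target))
  if (!length(lab)) "N/A" else paste(lab, collapse = "; ")
}

#' Score the removal of a set of edges
#'
#' Sets the coefficients of the removed edges to zero (no refit),
#' recomputes the simulation error against the data and the robustness
#' statistics against the reduced model's own unperturbed simulation.
#'
#' @param net current [grn_network()].
#' @param params parameters fitted on `net`.
#' @param ds observed dataset on the model scale.
#' @param gene_edges,nlt_edges edges to remove (see [remove_edges()]).
#' @param rcfg a [robustness_config()].
#' @return `deletion_step` list: `label`, `removed`, `SE`, `RA`, `RSTD`,
#'   `n_failed`.
#' @export
score_removal <- function(net, params, ds, gene_edges = NULL,
                          nlt_edges = NULL, rcfg = robustness_config()) {
  red_net <- remove_edges(net, gene_edges, nlt_edges)  # validates presence
  red_par <- zero_removed(params, gene_edges, nlt_edges)
  x0 <- ds$values[, 1]
  bound <- 1e6 * max(abs(ds$values), 1)
  traj <- simulate_trajectory(red_par, net, x0, ds$times, div_bound = bound)
  SE <- simulation_error(traj, ds)
  if (traj$status == "ok") {
    rob <- robustness(net, red_par, ds, rcfg)
  } else {
    # unstable reduced model: report as unusable rather than erroring
    rob <- list(RA = Inf, RSTD = Inf, n_failed = rcfg$n_perturb)
  }
  structure(list(label = NA_character_,
                 removed = rr_label(gene_edges, nlt_edges),
                 removed_gene_edges = gene_edges,
                 removed_nlt_edges = nlt_edges,
                 SE = SE, RA = rob$RA, RSTD = rob$RSTD,
                 n_failed = rob$n_failed, network = red_net),
            class = "deletion_step")
}

#' Greedy edge-deletion network reduction
#'
#' Phase 1 iterates over NLT->gene edges, phase 2 over gene->gene edges.
#' Each iteration scores every single-edge removal (robustness at the
#' reduced screening `N`); when no single removal changes the simulation
#' error by more than `delta`, up to `batch_max` inert removals are
#' batched into one step (mirroring the removal of several product-term
#' regulations at once when singles leave the error unchanged). The
#' candidate minimizing the simulation-error change is removed permanently
#' (ties: smaller RA), and the accepted step is re-scored at the full `N`.
#' Deletion stops when the best candidate would push the simulation error
#' above `(1 + tau) * SE_OES` AND the robust average above
#' `(1 + tau) * RA_OES`.
#'
#' @param net the fitted [grn_network()].
#' @param fit a `fit_result` from [ga_fit()] for `net`.
#' @param ds observed [gene_dataset()] (raw scale; the fit's normalization
#'   is re-applied internally).
#' @param rcfg a [robustness_config()] (its `n_perturb` is the full N).
#' @param tau relative worsening threshold of the stop rule (default 0.10).
#' @param delta simulation-error change below which a removal counts as
#'   inert (default 1e-4).
#' @param batch_max maximum batched inert removals per step (default 3).
#' @param screen_n reduced robustness N for candidate screening
#'   (default 500).
#' @return object of class `deletion_trace`: list of steps, the first
#'   labelled `OES` (no removal), then `DEL1`, `DEL2`, ...; the final
#'   network is attached as attribute `"network"`.
#' @export
greedy_prune <- function(net, fit, ds, rcfg = robustness_config(),
                         tau = 0.10, delta = 1e-4, batch_max = 3,
                         screen_n = 500) {
  stopifnot(inherits(fit, "fit_result"))
  dsn <- normalize_dataset(ds, fit$normalize)
  params <- fit$params
  scfg <- rcfg
  scfg$n_perturb <- screen_n
  x0 <- dsn$values[, 1]
  bound <- 1e6 * max(abs(dsn$values), 1)
  base_traj <- simulate_trajectory(params, net, x0, dsn$times,
                                   div_bound = bound)
  base_rob <- robustness(net, params, dsn, rcfg)
  oes <- list(label = "OES", removed = "N/A",
              SE = simulation_error(base_traj, dsn),
              RA = base_rob$RA, RSTD = base_rob$RSTD,
              n_failed = base_rob$n_failed)
  steps <- list(oes)
  cur_net <- net
  cur_par <- params
  se0 <- oes$SE; ra0 <- oes$RA
  for (phase in c("nlt", "gene")) {
    repeat {
      pool <- if (phase == "nlt") cur_net$nlt_edges else cur_net$gene_edges
      if (nrow(pool) == 0) break
      singles <- lapply(seq_len(nrow(pool)), function(i) {
        e <- pool[i, , drop = FALSE]
        if (phase == "nlt")
          score_removal(cur_net, cur_par, dsn, nlt_edges = e, rcfg = scfg)
        else
          score_removal(cur_net, cur_par, dsn, gene_edges = e, rcfg = scfg)
      })
      se <- vapply(singles, `[[`, numeric(1), "SE")
      ra <- vapply(singles, `[[`, numeric(1), "RA")
      dse <- abs(se - oes$SE)
      chosen <- NULL
      if (all(dse <= delta) && nrow(pool) > 1) {
        # inert singles: batch the smallest-change candidates as one step
        take <- head(order(dse, ra), min(batch_max, nrow(pool)))
        e <- pool[take, , drop = FALSE]
        chosen <- if (phase == "nlt")
          score_removal(cur_net, cur_par, dsn, nlt_edges = e, rcfg = scfg)
        else
          score_removal(cur_net, cur_par, dsn, gene_edges = e, rcfg = scfg)
      } else {
        best <- order(dse, ra)[1]
        chosen <- singles[[best]]
      }
      worse_se <- chosen$SE > (1 + tau) * se0
      worse_ra <- chosen$RA > (1 + tau) * ra0
      if (worse_se && worse_ra) break
      # accept: rescore at the full N and update state
      accepted <- if (phase == "nlt")
        score_removal(cur_net, cur_par, dsn,
                      nlt_edges = chosen$removed_nlt_edges, rcfg = rcfg)
      else
        score_removal(cur_net, cur_par, dsn,
                      gene_edges = chosen$removed_gene_edges, rcfg = rcfg)
      accepted$label <- paste0("DEL", length(steps))
      cur_par <- drop_removed(cur_par, accepted$removed_gene_edges,
                              accepted$removed_nlt_edges)
      cur_net <- accepted$network
      steps <- c(steps, list(accepted))
    }
  }
  out <- structure(steps, class = "deletion_trace")
  attr(out, "network") <- cur_net
  out
}

#' @export
as.data.frame.deletion_trace <- function(x, ...) {
  data.frame(Model = vapply(x, `[[`, "", "label"),
             RR = vapply(x, `[[`, "", "removed"),
             SE = vapply(x, `[[`, numeric(1), "SE"),
             RA = vapply(x, `[[`, numeric(1), "RA"),
             RSTD = vapply(x, `[[`, numeric(1), "RSTD"))
}

#' @export
print.deletion_trace <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Apply a recorded deletion trace to a network
#'
#' Replays the removed-regulation lists of a trace (or any list of steps
#' with `removed_gene_edges` / `removed_nlt_edges` entries) against a
#' network, returning the reduced network. Used to audit traces: edge
#' counts after replay must equal the initial count minus the total
#' removed.
#'
#' @param net a [grn_network()].
#' @param steps a `deletion_trace` or list of steps.
#' @return the reduced network.
#' @export
apply_trace <- function(net, steps) {
  for (s in steps) {
    if (identical(s$label, "OES")) next
    net <- remove_edges(net, s$removed_gene_edges, s$removed_nlt_edges)
  }
  net
}
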