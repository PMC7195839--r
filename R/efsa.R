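# Extended forward search over a Gaussian graphical model: covariance
# assembly, iterative proportional scaling (IPS / IMLEA) under a graph's
# zero-pattern, chi-square(1) deviance tests for single added edges, the
# two-stage forward selection (gene-gene first, then NLT->gene capped at
# the gene-edge count) and the deterministic acyclic orientation.

#' Forward-search configuration
#'
#' @param cutoff p-value threshold for adding an edge (default 0.1).
#' @param nlt_cap_mode `"match_m1"` caps stage-2 NLT edges at the stage-1
#'   gene edge count; `"none"` disables the cap.
#' @param standardize standardize rows to mean 0 / variance 1 before
#'   covariance assembly (default TRUE; deviance differences are invariant
#'   to per-variable scaling, this only conditions the numerics).
#' @param ips_tol IPS convergence tolerance on the constraint residual.
#' @param ips_max_iter maximum IPS sweeps.
#' @return list of class `efsa_config`.
#' @export
efsa_config <- function(cutoff = 0.1, nlt_cap_mode = c("match_m1", "none"),
                        standardize = TRUE, ips_tol = 1e-8,
                        ips_max_iter = 5000) {
  nlt_cap_mode <- match.arg(nlt_cap_mode)
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must be in (0, 1)")
  structure(list(cutoff = cutoff, nlt_cap_mode = nlt_cap_mode,
                 standardize = standardize, ips_tol = ips_tol,
                 ips_max_iter = ips_max_iter), class = "efsa_config")
}

#' Standardize matrix rows to mean 0, sample variance 1
#'
#' @param mat numeric matrix (variables in rows, observations in columns).
#' @return list `values` (standardized matrix), `mean`, `sd` per row.
#' @export
standardize_rows <- function(mat) {
  mat <- as.matrix(mat)
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  zero <- which(sdv == 0)
  if (length(zero)) {
    nm <- rownames(mat)[zero[1]]
    stop("zero-variance row: ", if (!is.null(nm)) nm else zero[1])
  }
  list(values = (mat - mu) / sdv, mean = mu, sd = sdv)
}

#' Assemble the blocked sample covariance of genes and NLTs
#'
#' The N x N unbiased sample covariance (divisor n_obs - 1) of the m gene
#' rows and n NLT rows, partitioned as M = [[A, B], [B', C]].
#'
#' @param mat N x M matrix, gene rows first.
#' @param m number of gene rows.
#' @param n_obs number of observations (defaults to `ncol(mat)`).
#' @return list of class `cov_model`: `M` (full matrix), `A`, `B`, `C`
#'   blocks, `m`, `n`, `n_obs`.
#' @export
sample_covariance <- function(mat, m, n_obs = ncol(mat)) {
  if (ncol(mat) < 2) stop("need at least 2 observations")
  S <- cov(t(mat))
  N <- nrow(mat)
  gi <- seq_len(m); ni <- setdiff(seq_len(N), gi)
  structure(list(M = S, A = S[gi, gi, drop = FALSE],
                 B = S[gi, ni, drop = FALSE], C = S[ni, ni, drop = FALSE],
                 m = m, n = N - m, n_obs = n_obs), class = "cov_model")
}

as_cov_matrix <- function(S) {
  if (inherits(S, "cov_model")) S$M else as.matrix(S)
}

# edges: k x 2 integer matrix (u < v). Always returned that way.
canon_edges <- function(edges) {
  if (is.null(edges) || length(edges) == 0)
    return(matrix(integer(), 0, 2))
  edges <- matrix(as.integer(edges), ncol = 2)
  cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
}

# Maximal cliques of an undirected graph by Bron-Kerbosch with pivoting.
# Returns a list of integer vectors (only cliques of size >= 2; isolated
# vertices are handled separately by the caller).
maximal_cliques <- function(N, edges) {
  adj <- vector("list", N)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      if (length(R) >= 2) out[[length(out) + 1L]] <<- sort(R)
      return(invisible())
    }
    pivot_pool <- c(P, X)
    pivot <- pivot_pool[which.max(vapply(pivot_pool, function(u)
      sum(P %in% adj[[u]]), numeric(1)))]
    for (v in setdiff(P, adj[[pivot]])) {
      bk(c(R, v), intersect(P, adj[[v]]), intersect(X, adj[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  touched <- sort(unique(as.vector(edges)))
  bk(integer(0), touched, integer(0))
  out
}

#' Constrained Gaussian MLE by iterative proportional scaling
#'
#' Computes the maximum-likelihood covariance under the graphical model
#' whose precision matrix is zero outside the given undirected edge set:
#' the fit matches `S` on the diagonal and on every edge, and the inverse
#' is exactly zero on non-adjacent pairs. Iterates proportional-scaling
#' updates over the maximal cliques of the graph in precision space (a
#' single sweep is exact for decomposable graphs), with Woodbury updates
#' of the covariance, until the maximum absolute constraint residual
#' falls below `tol`.
#'
#' @param S symmetric sample covariance (or a `cov_model`).
#' @param edges k x 2 matrix of undirected edges (indices into S).
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter maximum number of sweeps.
#' @return fitted covariance matrix with attributes `iterations` and
#'   `logdet` (log-determinant of the fit).
#' @export
ips_fit <- function(S, edges, tol = 1e-8, max_iter = 5000) {
  S <- as_cov_matrix(S)
  N <- nrow(S)
  dS <- diag(S)
  if (any(dS <= 0)) stop("covariance diagonal must be strictly positive")
  edges <- canon_edges(edges)
  if (nrow(edges)) {
    if (any(edges < 1 | edges > N)) stop("edge index out of range")
    if (any(edges[, 1] == edges[, 2])) stop("self-edge not allowed")
  }
  if (nrow(edges) == 0) {
    Sigma <- diag(dS, N)
    attr(Sigma, "iterations") <- 0L
    attr(Sigma, "logdet") <- sum(log(dS))
    return(Sigma)
  }
  cliques <- maximal_cliques(N, edges)
  Scc_inv <- vector("list", length(cliques))
  for (ci in seq_along(cliques)) {
    cc <- cliques[[ci]]
    ch <- tryCatch(chol(S[cc, cc, drop = FALSE]), error = function(e) NULL)
    if (is.null(ch))
      stop("singular clique submatrix for clique (",
           paste(cc, collapse = ", "), ")")
    Scc_inv[[ci]] <- chol2inv(ch)
  }
  K <- diag(1 / dS, N)
  Sigma <- diag(dS, N)
  resid <- Inf
  # Phase 1: proportional-scaling sweeps. One sweep is exact for
  # decomposable graphs; for interlocking cliques on near-collinear data
  # the linear rate can approach 1, so after a bounded number of sweeps we
  # hand the (feasible, PD) iterate to a Newton ascent of the concave
  # constrained log-likelihood, which is insensitive to that conditioning.
  sweeps <- min(max_iter, 10L)
  for (iter in seq_len(sweeps)) {
    for (ci in seq_along(cliques)) {
      cc <- cliques[[ci]]
      Wcc <- Sigma[cc, cc, drop = FALSE]
      D <- Scc_inv[[ci]] - chol2inv(chol(Wcc))
      K[cc, cc] <- K[cc, cc] + D
      U <- Sigma[, cc, drop = FALSE]
      mid <- solve(diag(length(cc)) + D %*% Wcc, D)
      Sigma <- Sigma - U %*% mid %*% t(U)
      Sigma <- (Sigma + t(Sigma)) / 2
    }
    # resync covariance from precision so Woodbury round-off cannot
    # accumulate across sweeps
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (!is.null(ch)) Sigma <- chol2inv(ch)
    resid <- max(max(abs(diag(Sigma) - dS)), max(abs(Sigma[edges] - S[edges])))
    if (resid < tol) {
      attr(Sigma, "iterations") <- iter
      attr(Sigma, "residual") <- resid
      attr(Sigma, "logdet") <-
        if (!is.null(ch)) -2 * sum(log(diag(ch))) else
          as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
      return(Sigma)
    }
  }
  # Phase 2: damped Newton on the free precision entries (diagonal + edges),
  # maximizing logdet(K) - tr(S K); the gradient in each free position is
  # the margin residual, so the stopping rule is unchanged.
  U <- c(seq_len(N), edges[, 1])
  V <- c(seq_len(N), edges[, 2])
  kv <- c(rep(1, N), rep(2, nrow(edges)))   # multiplicity of each position
  obj <- function(K) {
    ch <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(ch)) return(list(ok = FALSE))
    list(ok = TRUE, ch = ch, value = 2 * sum(log(diag(ch))) - sum(S * K))
  }
  cur <- obj(K)
  if (!cur$ok) stop("IPS iterate lost positive definiteness")
  for (it in seq_len(100L)) {
    Sigma <- chol2inv(cur$ch)
    gvec <- kv * (Sigma[cbind(U, V)] - S[cbind(U, V)])
    resid <- max(abs(Sigma[cbind(U, V)] - S[cbind(U, V)]))
    if (resid < tol) {
      out <- Sigma
      attr(out, "iterations") <- sweeps + it
      attr(out, "residual") <- resid
      attr(out, "logdet") <- -2 * sum(log(diag(cur$ch)))
      return(out)
    }
    H <- 0.5 * (kv %o% kv) *
      (Sigma[U, U] * Sigma[V, V] + Sigma[U, V] * Sigma[V, U])
    dx <- tryCatch(solve(H, gvec), error = function(e) NULL)
    if (is.null(dx)) break
    step <- 1
    repeat {
      Knew <- K
      idx <- cbind(U, V)
      Knew[idx] <- Knew[idx] + step * dx
      Knew[idx[, 2:1]] <- Knew[idx]
      nxt <- obj(Knew)
      if (nxt$ok && nxt$value >= cur$value - 1e-12 * abs(cur$value)) {
        K <- Knew
        cur <- nxt
        break
      }
      step <- step / 2
      if (step < 1e-12) break
    }
    if (step < 1e-12) break
  }
  stop("constrained MLE did not converge (last residual ",
       format(resid, digits = 4), ")")
}

#' Deviance of a fitted graphical model
#'
#' `n_obs * (log det(Sigma_hat) - log det(S))`, zero for the saturated
#' model. Only differences between nested fits are used by the edge tests,
#' where the `S` term cancels.
#'
#' @param S sample covariance (must be positive definite here).
#' @param sigma_hat IPS-fitted covariance.
#' @param n_obs observation count.
#' @return non-negative deviance.
#' @export
ggm_deviance <- function(S, sigma_hat, n_obs) {
  S <- as_cov_matrix(S)
  for (nm in c("S", "sigma_hat")) {
    mat <- if (nm == "S") S else sigma_hat
    ev <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0) stop(nm, " is not positive definite")
  }
  ldS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  ldF <- as.numeric(determinant(sigma_hat, logarithm = TRUE)$modulus)
  n_obs * (ldF - ldS)
}

#' Chi-square test for a single candidate edge
#'
#' Fits the model with and without the candidate; the deviance difference
#' `n_obs * (logdet(fit_without) - logdet(fit_with))` is referred to the
#' chi-square distribution with one degree of freedom (upper tail).
#' Negative numerical differences are clipped to zero (p = 1).
#'
#' @param S sample covariance (`cov_model` or matrix).
#' @param edges current permanent edge set (k x 2).
#' @param edge length-2 integer vector, the candidate.
#' @param n_obs observation count used in the deviance scaling.
#' @param cfg an [efsa_config()] (supplies IPS tolerances).
#' @param fit0 optional pre-computed fit of the current graph.
#' @return list `edge`, `deviance_difference`, `p_value`.
#' @export
edge_pvalue <- function(S, edges, edge, n_obs, cfg = efsa_config(),
                        fit0 = NULL) {
  S <- as_cov_matrix(S)
  edges <- canon_edges(edges)
  edge <- sort(as.integer(edge))
  if (nrow(edges) && any(edges[, 1] == edge[1] & edges[, 2] == edge[2]))
    stop("candidate edge already in the graph")
  if (is.null(fit0))
    fit0 <- ips_fit(S, edges, cfg$ips_tol, cfg$ips_max_iter)
  fit1 <- ips_fit(S, rbind(edges, edge), cfg$ips_tol, cfg$ips_max_iter)
  dd <- n_obs * (attr(fit0, "logdet") - attr(fit1, "logdet"))
  dd <- max(dd, 0)
  list(edge = edge, deviance_difference = dd,
       p_value = pchisq(dd, df = 1, lower.tail = FALSE))
}

#' Greedy forward search over candidate edges
#'
#' Each round tests every remaining candidate against the current graph,
#' then permanently adds the edge with the smallest p-value if it is below
#' the cutoff (ties: larger deviance difference, then lexicographic edge
#' order). Stops when the smallest p-value reaches the cutoff or the cap
#' is hit. The addition order is the edge's selection rank.
#'
#' @param S sample covariance (`cov_model` or matrix).
#' @param g0 starting edge set (k x 2 matrix, possibly empty).
#' @param candidates c x 2 matrix of candidate edges, all absent from `g0`.
#' @param cfg an [efsa_config()].
#' @param n_obs observation count (defaults to `S$n_obs` for `cov_model`).
#' @param cap optional maximum number of edges to add.
#' @return list of class `graph_state`: `edges` (all permanent edges
#'   including `g0`), `provenance` (data.frame u, v, deviance, p_value,
#'   rank for the added edges in order).
#' @export
forward_search <- function(S, g0, candidates, cfg = efsa_config(),
                           n_obs = NULL, cap = NULL) {
  if (is.null(n_obs)) {
    if (!inherits(S, "cov_model"))
      stop("n_obs must be given when S is a plain matrix")
    n_obs <- S$n_obs
  }
  Sm <- as_cov_matrix(S)
  g <- canon_edges(g0)
  cand <- canon_edges(candidates)
  if (nrow(cand)) {
    key <- function(e) paste(e[, 1], e[, 2])
    if (any(key(cand) %in% key(g)))
      stop("candidate already present in the starting graph")
    if (anyDuplicated(key(cand))) stop("duplicate candidates")
  }
  prov <- data.frame(u = integer(), v = integer(), deviance = numeric(),
                     p_value = numeric(), rank = integer())
  if (is.null(cap)) cap <- nrow(cand)
  while (nrow(cand) > 0 && nrow(prov) < cap) {
    fit0 <- ips_fit(Sm, g, cfg$ips_tol, cfg$ips_max_iter)
    tests <- lapply(seq_len(nrow(cand)), function(i)
      edge_pvalue(Sm, g, cand[i, ], n_obs, cfg, fit0 = fit0))
    p <- vapply(tests, `[[`, numeric(1), "p_value")
    dd <- vapply(tests, `[[`, numeric(1), "deviance_difference")
    # smallest p; ties -> larger deviance, then lexicographic edge order
    ord <- order(p, -dd, cand[, 1], cand[, 2])
    best <- ord[1]
    if (p[best] >= cfg$cutoff) break
    g <- rbind(g, cand[best, , drop = FALSE])
    prov <- rbind(prov, data.frame(u = cand[best, 1], v = cand[best, 2],
                                   deviance = dd[best], p_value = p[best],
                                   rank = nrow(prov) + 1L))
    cand <- cand[-best, , drop = FALSE]
  }
  structure(list(edges = g, provenance = prov), class = "graph_state")
}

#' Orient an undirected gene graph into a DAG
#'
#' Surrogate for published orientation rule sets: each undirected edge is
#' directed from the endpoint that first appears in the forward-search
#' provenance log to the later one (nodes absent from the log rank after
#' all logged nodes, ties broken by input gene order). Orientation along
#' this total order guarantees acyclicity and determinism.
#'
#' @param g a `graph_state` from [forward_search()] over gene-gene edges.
#' @param m number of genes (defaults to the largest index seen).
#' @return data.frame `source`, `target` (integer gene indices), plus the
#'   provenance `deviance`, `p_value`, `rank` columns.
#' @export
orient_genes <- function(g, m = NULL) {
  edges <- canon_edges(g$edges)
  prov <- g$provenance
  if (nrow(edges) == 0)
    return(data.frame(source = integer(), target = integer(),
                      deviance = numeric(), p_value = numeric(),
                      rank = integer()))
  if (is.null(m)) m <- max(edges)
  appearance <- rep(Inf, m)
  t <- 0
  for (r in seq_len(nrow(prov))) {
    for (node in c(prov$u[r], prov$v[r])) {
      t <- t + 1
      if (!is.finite(appearance[node])) appearance[node] <- t
    }
  }
  # total order: appearance time, then gene index
  rank_of <- order(order(appearance, seq_len(m)))
  src <- ifelse(rank_of[edges[, 1]] < rank_of[edges[, 2]],
                edges[, 1], edges[, 2])
  dst <- ifelse(rank_of[edges[, 1]] < rank_of[edges[, 2]],
                edges[, 2], edges[, 1])
  out <- data.frame(source = src, target = dst)
  if (nrow(prov)) {
    key <- paste(edges[, 1], edges[, 2])
    pk <- paste(prov$u, prov$v)
    idx <- match(key, pk)
    out$deviance <- prov$deviance[idx]
    out$p_value <- prov$p_value[idx]
    out$rank <- prov$rank[idx]
  } else {
    out$deviance <- NA_real_; out$p_value <- NA_real_; out$rank <- NA_integer_
  }
  out
}

#' Run the two-stage extended forward search
#'
#' Stage 1 forward-searches the gene-gene candidate pairs and orients the
#' selected skeleton into a DAG (`m1` directed gene edges). Stage 2
#' forward-searches the gene-NLT candidate positions starting from the
#' stage-1 graph, capped at `m1` additions, every selected edge directed
#' NLT -> gene. NLT-NLT edges are never candidates (the NLT block of the
#' graph stays the identity). NLTs never selected are reported as isolated.
#'
#' @param ds a [gene_dataset()] with at least 2 genes and 3 time points.
#' @param cfg an [efsa_config()].
#' @return a [grn_network()] with selection ranks and p-values; stage
#'   details are attached as attribute `"stages"`.
#' @export
run_efsa <- function(ds, cfg = efsa_config()) {
  stopifnot(inherits(ds, "gene_dataset"))
  m <- length(ds$genes)
  if (m < 2) stop("need at least 2 genes")
  if (length(ds$times) < 3) stop("need at least 3 time points")
  aug <- build_augmented(ds)
  mat <- aug$values
  if (cfg$standardize) {
    mat <- tryCatch(standardize_rows(mat)$values, error = function(e)
      stop("degenerate data: ", conditionMessage(e)))
  }
  S <- sample_covariance(mat, m, n_obs = length(ds$times))
  n <- S$n
  # stage 1: gene-gene pairs
  gene_cand <- as.matrix(enumerate_nlts(m))  # all unordered gene pairs
  s1 <- forward_search(S, NULL, gene_cand, cfg)
  directed <- orient_genes(s1, m)
  m1 <- nrow(directed)
  # stage 2: gene-NLT positions, starting from the stage-1 graph
  nlt_cand <- cbind(rep(seq_len(m), each = n),
                    rep(m + seq_len(n), times = m))
  cap <- if (cfg$nlt_cap_mode == "match_m1") m1 else NULL
  s2 <- forward_search(S, s1$edges, nlt_cand, cfg, cap = cap)
  p2 <- s2$provenance
  # in stage 2, u is the gene (u <= m), v the NLT (v > m) after canon
  nlt_idx <- p2$v - m
  nlt_pairs <- aug$nlt[nlt_idx, , drop = FALSE]
  nlt_edges <- data.frame(first = ds$genes[nlt_pairs$first],
                          second = ds$genes[nlt_pairs$second],
                          target = ds$genes[p2$u],
                          rank = p2$rank, p_value = p2$p_value)
  gene_edges <- data.frame(source = ds$genes[directed$source],
                           target = ds$genes[directed$target],
                           rank = directed$rank, p_value = directed$p_value)
  gene_edges <- gene_edges[order(gene_edges$rank), , drop = FALSE]
  selected_nlts <- unique(nlt_idx)
  isolated <- setdiff(seq_len(n), selected_nlts)
  net <- grn_network(ds$genes, gene_edges, nlt_edges,
                     isolated_nlts = nlt_label(ds$genes,
                                               aug$nlt$first[isolated],
                                               aug$nlt$second[isolated]))
  attr(net, "stages") <- list(stage1 = s1, stage2 = s2)
  net
}
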