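# Core data containers: time grids, expression datasets, non-linear-term
# (NLT) augmentation, inferred networks and ODE model parameters.

#' Validate an observation time grid
#'
#' A time grid is a plain numeric vector of observation times in hours.
#' It must be strictly increasing, finite, non-negative and of length >= 2.
#'
#' @param times numeric vector of observation times (hours).
#' @return the validated numeric vector, invisibly classed as used internally.
#' @export
as_time_grid <- function(times) {
  times <- as.numeric(times)
  if (length(times) < 2L)
    stop("time grid needs at least 2 points, got ", length(times))
  if (any(!is.finite(times)))
    stop("time grid contains non-finite values")
  if (any(times < 0))
    stop("time grid contains negative times")
  if (any(diff(times) <= 0))
    stop("time grid must be strictly increasing (monotonicity violated at index ",
         which(diff(times) <= 0)[1] + 1L, ")")
  times
}

#' Construct a gene expression dataset
#'
#' Bundles `m` uniquely named genes, an observation time grid of `M` points
#' and the `m x M` matrix of (already normalized) expression intensities
#' `x_ij` for gene i at time point j. Values must be finite and
#' non-negative; the loader performs no normalization.
#'
#' @param genes character vector of `m` unique gene names.
#' @param times observation time grid (hours), see [as_time_grid()].
#' @param values numeric `m x M` matrix of expression levels.
#' @return an object of class `gene_dataset` with fields `genes`, `times`,
#'   `values` (dimnames set to genes x times).
#' @export
gene_dataset <- function(genes, times, values) {
  genes <- as.character(genes)
  times <- as_time_grid(times)
  values <- as.matrix(values)
  if (anyDuplicated(genes))
    stop("duplicate gene names: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  if (nrow(values) != length(genes))
    stop("row count (", nrow(values), ") does not match gene-name count (",
         length(genes), ")")
  if (ncol(values) != length(times))
    stop("column count (", ncol(values), ") does not match time-grid length (",
         length(times), ")")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite entries")
  if (any(values < 0))
    stop("expression matrix contains negative entries")
  storage.mode(values) <- "double"
  dimnames(values) <- list(genes, format(times, trim = TRUE))
  structure(list(genes = genes, times = times, values = values),
            class = "gene_dataset")
}

#' @export
print.gene_dataset <- function(x, ...) {
  cat("<gene_dataset> ", length(x$genes), " genes x ", length(x$times),
      " time points (", x$times[1], "-", x$times[length(x$times)], " h)\n",
      sep = "")
  invisible(x)
}

#' Enumerate all pairwise non-linear terms
#'
#' Every unordered gene pair \{G_j, G_k\} (j < k) defines one non-linear
#' term (NLT), the product series standing in for a protein heterodimer or
#' a synergistic effect. Pairs are returned in lexicographic order by
#' (j, k); this ordering is fixed across the whole package.
#'
#' @param m number of genes (>= 2).
#' @return data.frame with integer columns `first` < `second`,
#'   `m*(m-1)/2` rows.
#' @examples
#' nrow(enumerate_nlts(11)) # 55
#' @export
enumerate_nlts <- function(m) {
  if (!is.numeric(m) || length(m) != 1L || m != round(m) || m < 2)
    stop("m must be a single integer >= 2, got ", deparse(m))
  m <- as.integer(m)
  first <- rep(seq_len(m - 1L), times = (m - 1L):1L)
  second <- unlist(lapply(seq_len(m - 1L), function(j) (j + 1L):m))
  data.frame(first = first, second = second)
}

nlt_label <- function(genes, first, second) {
  paste0(genes[first], ":", genes[second])
}

#' Augment a dataset with all non-linear term product rows
#'
#' Appends, below the `m` gene rows, one row per unordered gene pair holding
#' the elementwise product `y_klj = x_kj * x_lj`. Row `m + p` corresponds to
#' `enumerate_nlts(m)[p, ]`.
#'
#' @param ds a [gene_dataset()].
#' @return object of class `augmented_dataset`: fields `base`, `nlt`
#'   (pair index data.frame), `values` (`N x M`, `N = m + m(m-1)/2`),
#'   `labels` (gene names followed by "A:B" NLT labels).
#' @export
build_augmented <- function(ds) {
  stopifnot(inherits(ds, "gene_dataset"))
  m <- length(ds$genes)
  if (m < 2) stop("need at least 2 genes to form non-linear terms")
  nlt <- enumerate_nlts(m)
  prod_rows <- ds$values[nlt$first, , drop = FALSE] *
    ds$values[nlt$second, , drop = FALSE]
  bad <- which(!is.finite(prod_rows), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    p <- bad[1, 1]
    stop("non-finite product for pair (", ds$genes[nlt$first[p]], ", ",
         ds$genes[nlt$second[p]], ")")
  }
  values <- rbind(ds$values, prod_rows)
  labels <- c(ds$genes, nlt_label(ds$genes, nlt$first, nlt$second))
  rownames(values) <- labels
  structure(list(base = ds, nlt = nlt, values = values, labels = labels),
            class = "augmented_dataset")
}

#' Average replicate datasets
#'
#' Elementwise arithmetic mean of replicate expression matrices. Replicates
#' must share identical gene names and time grids; no interpolation is
#' attempted.
#'
#' @param replicates list of [gene_dataset()] objects (length >= 1).
#' @return a [gene_dataset()] holding the mean.
#' @export
average_replicates <- function(replicates) {
  if (!is.list(replicates) || length(replicates) < 1L)
    stop("need a non-empty list of datasets")
  lapply(replicates, function(d) stopifnot(inherits(d, "gene_dataset")))
  ref <- replicates[[1]]
  for (i in seq_along(replicates)[-1]) {
    d <- replicates[[i]]
    if (!identical(d$genes, ref$genes))
      stop("replicate ", i, " gene names differ from replicate 1: ",
           paste(setdiff(union(d$genes, ref$genes),
                         intersect(d$genes, ref$genes)), collapse = ", "))
    if (!isTRUE(all.equal(d$times, ref$times, tolerance = 0)))
      stop("replicate ", i, " time grid differs from replicate 1")
  }
  mean_values <- Reduce(`+`, lapply(replicates, `[[`, "values")) /
    length(replicates)
  gene_dataset(ref$genes, ref$times, mean_values)
}

#' Normalize an expression dataset for model fitting
#'
#' `per_gene_max` divides each gene row by its maximum (the default used
#' before genetic-algorithm fitting), `zscore` centres and scales each row,
#' `none` is the identity. Note `zscore` produces negative values, so the
#' result is returned as a raw list rather than a strict [gene_dataset()]
#' when the transform breaks non-negativity.
#'
#' @param ds a [gene_dataset()].
#' @param method one of `"per_gene_max"`, `"none"`, `"zscore"`.
#' @return a `gene_dataset`-shaped object on the transformed scale.
#' @export
normalize_dataset <- function(ds, method = c("per_gene_max", "none", "zscore")) {
  method <- match.arg(method)
  stopifnot(inherits(ds, "gene_dataset"))
  if (method == "none") return(ds)
  v <- ds$values
  if (method == "per_gene_max") {
    mx <- apply(v, 1, max)
    if (any(mx <= 0))
      stop("per_gene_max normalization impossible: gene(s) with max <= 0: ",
           paste(ds$genes[mx <= 0], collapse = ", "))
    v <- v / mx
    return(gene_dataset(ds$genes, ds$times, v))
  }
  # zscore: may go negative, bypass the non-negativity check
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  if (any(sdv == 0))
    stop("zscore normalization impossible: constant gene row(s): ",
         paste(ds$genes[sdv == 0], collapse = ", "))
  out <- gene_dataset(ds$genes, ds$times, matrix(1, nrow(v), ncol(v)))
  out$values <- (v - mu) / sdv
  dimnames(out$values) <- dimnames(v)
  out
}

#' Construct an inferred regulatory network
#'
#' Holds the directed gene->gene edges (the oriented stage-1 selection,
#' `A_s`) and the directed NLT->gene edges (stage-2 selection, `B'_s`),
#' each with its forward-search selection rank and chi-square p-value.
#'
#' @param genes character vector of gene names the network is over.
#' @param gene_edges data.frame with character columns `source`, `target`
#'   and numeric `rank`, `p_value` (zero-row data.frame allowed).
#' @param nlt_edges data.frame with character columns `first`, `second`
#'   (the NLT pair, `first` < `second` in gene order), `target`, and
#'   numeric `rank`, `p_value`.
#' @param isolated_nlts optional character vector of "A:B" labels of NLTs
#'   to which no edge was attached.
#' @return object of class `grn_network`.
#' @export
grn_network <- function(genes, gene_edges = NULL, nlt_edges = NULL,
                        isolated_nlts = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene names")
  empty_ge <- data.frame(source = character(), target = character(),
                         rank = numeric(), p_value = numeric())
  empty_ne <- data.frame(first = character(), second = character(),
                         target = character(), rank = numeric(),
                         p_value = numeric())
  if (is.null(gene_edges) || nrow(gene_edges) == 0) gene_edges <- empty_ge
  if (is.null(nlt_edges) || nrow(nlt_edges) == 0) nlt_edges <- empty_ne
  gene_edges <- as.data.frame(gene_edges)
  nlt_edges <- as.data.frame(nlt_edges)
  stopifnot(all(c("source", "target") %in% names(gene_edges)),
            all(c("first", "second", "target") %in% names(nlt_edges)))
  for (col in c("rank", "p_value")) {
    if (is.null(gene_edges[[col]])) gene_edges[[col]] <- NA_real_
    if (is.null(nlt_edges[[col]])) nlt_edges[[col]] <- NA_real_
  }
  chk <- function(x, what) {
    bad <- setdiff(x, genes)
    if (length(bad)) stop(what, " references unknown gene(s): ",
                          paste(unique(bad), collapse = ", "))
  }
  chk(gene_edges$source, "gene edge source")
  chk(gene_edges$target, "gene edge target")
  chk(nlt_edges$first, "nlt edge")
  chk(nlt_edges$second, "nlt edge")
  chk(nlt_edges$target, "nlt edge target")
  if (any(gene_edges$source == gene_edges$target))
    stop("self-loop gene edge not allowed")
  gi <- match(nlt_edges$first, genes)
  gj <- match(nlt_edges$second, genes)
  if (any(gi >= gj))
    stop("NLT pair must be stored canonically (first before second in gene order)")
  if (anyDuplicated(paste(gene_edges$source, gene_edges$target)))
    stop("duplicate gene edges")
  if (anyDuplicated(paste(nlt_edges$first, nlt_edges$second, nlt_edges$target)))
    stop("duplicate NLT edges")
  if (nrow(nlt_edges) > nrow(gene_edges))
    stop("NLT edge count (", nrow(nlt_edges),
         ") exceeds gene edge count (", nrow(gene_edges), "): n1 <= m1 required")
  if (!is_acyclic_edges(genes, gene_edges))
    stop("gene edge subgraph contains a cycle")
  rownames(gene_edges) <- NULL
  rownames(nlt_edges) <- NULL
  structure(list(genes = genes, gene_edges = gene_edges,
                 nlt_edges = nlt_edges,
                 isolated_nlts = as.character(isolated_nlts)),
            class = "grn_network")
}

#' @export
print.grn_network <- function(x, ...) {
  cat("<grn_network> ", length(x$genes), " genes, ",
      nrow(x$gene_edges), " gene->gene edges, ",
      nrow(x$nlt_edges), " NLT->gene edges",
      if (length(x$isolated_nlts)) paste0(", ", length(x$isolated_nlts),
                                          " isolated NLTs"), "\n", sep = "")
  invisible(x)
}

# Kahn topological check on the directed gene-edge subgraph.
is_acyclic_edges <- function(genes, gene_edges) {
  m <- length(genes)
  if (nrow(gene_edges) == 0) return(TRUE)
  src <- match(gene_edges$source, genes)
  dst <- match(gene_edges$target, genes)
  indeg <- tabulate(dst, nbins = m)
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    out <- which(src == v)
    for (w in dst[out]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
    src[out] <- 0L
  }
  seen == m
}

#' Topological order of the gene subgraph
#'
#' @param net a [grn_network()].
#' @return character vector of gene names in a topological order of the
#'   directed gene->gene edges.
#' @export
topological_order <- function(net) {
  genes <- net$genes
  m <- length(genes)
  src <- match(net$gene_edges$source, genes)
  dst <- match(net$gene_edges$target, genes)
  indeg <- tabulate(dst, nbins = m)
  active <- rep(TRUE, length(src))
  order <- integer(0)
  queue <- which(indeg == 0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; order <- c(order, v)
    out <- which(active & src == v)
    active[out] <- FALSE
    for (w in dst[out]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(order) != m) stop("gene subgraph is not acyclic")
  genes[order]
}

#' Count free parameters of the ODE model on a network support
#'
#' One alpha per directed gene edge, one beta per NLT edge and one
#' degradation rate per gene: `m1 + n1 + m`. The fully connected model over
#' all `n = m(m-1)/2` NLTs has `m(m-1) + m*n + m = m(m+n)` parameters.
#'
#' @param net a [grn_network()], or `NULL` for the fully connected model.
#' @param m gene count.
#' @return integer parameter count.
#' @examples
#' count_parameters(NULL, 11) # 726, the fully connected 11-gene model
#' @export
count_parameters <- function(net, m) {
  m <- as.integer(m)
  if (is.null(net)) {
    n <- (m * (m - 1L)) %/% 2L
    return(m * (m + n))
  }
  stopifnot(inherits(net, "grn_network"))
  if (length(net$genes) != m)
    stop("network is over ", length(net$genes), " genes, not ", m)
  nrow(net$gene_edges) + nrow(net$nlt_edges) + m
}

#' Construct sparse ODE model parameters
#'
#' Coefficients of the non-linear ODE model on a network support:
#' `alpha` (gene->gene strengths), `beta` (NLT->gene strengths) and the
#' per-gene degradation rates `k`. Auto-regulation (`alpha_ii`) and
#' squared terms (`beta_ijj`) are structurally excluded.
#'
#' @param alpha data.frame `source`, `target`, `value`.
#' @param beta data.frame `first`, `second`, `target`, `value`.
#' @param k named numeric vector of positive degradation rates, one per gene.
#' @param net optional companion [grn_network()]; when given, the supports
#'   must be subsets of its edge sets.
#' @return object of class `grn_params`.
#' @export
grn_params <- function(alpha, beta, k, net = NULL) {
  empty_a <- data.frame(source = character(), target = character(),
                        value = numeric())
  empty_b <- data.frame(first = character(), second = character(),
                        target = character(), value = numeric())
  if (is.null(alpha) || nrow(alpha) == 0) alpha <- empty_a
  if (is.null(beta) || nrow(beta) == 0) beta <- empty_b
  alpha <- as.data.frame(alpha); beta <- as.data.frame(beta)
  if (is.null(names(k)) || anyDuplicated(names(k)))
    stop("k must be a named vector with unique gene names")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("degradation rates must be finite and > 0")
  if (any(alpha$source == alpha$target))
    stop("auto-regulation alpha_ii is excluded")
  if (nrow(beta) && any(beta$first == beta$second))
    stop("squared-term beta_ijj is excluded")
  if (!is.null(net)) {
    stopifnot(inherits(net, "grn_network"))
    key <- function(...) paste(..., sep = "\r")
    if (nrow(alpha) &&
        !all(key(alpha$source, alpha$target) %in%
             key(net$gene_edges$source, net$gene_edges$target)))
      stop("alpha support is not a subset of the network's gene edges")
    if (nrow(beta) &&
        !all(key(beta$first, beta$second, beta$target) %in%
             key(net$nlt_edges$first, net$nlt_edges$second,
                 net$nlt_edges$target)))
      stop("beta support is not a subset of the network's NLT edges")
    if (!setequal(names(k), net$genes) || length(k) != length(net$genes))
      stop("k must name exactly the network's genes")
    k <- k[net$genes]
  }
  rownames(alpha) <- NULL; rownames(beta) <- NULL
  structure(list(alpha = alpha, beta = beta, k = k), class = "grn_params")
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params> ", nrow(x$alpha), " alpha, ", nrow(x$beta), " beta, ",
      length(x$k), " degradation rates\n", sep = "")
  invisible(x)
}
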