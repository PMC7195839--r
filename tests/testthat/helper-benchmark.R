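# Shared fixtures, built in code.

# The documented 5-gene recovery benchmark: a hand-constructed world with
# couplings bounded away from zero, compensated negative regulations (so
# trajectories stay positive) and well-separated degradation rates, which
# makes every coefficient sign identifiable from the noise-free data.
make_benchmark <- function() {
  genes <- paste0("G", 1:5)
  net <- grn_network(
    genes,
    gene_edges = data.frame(source = c("G1", "G1", "G2", "G2", "G3"),
                            target = c("G2", "G3", "G3", "G4", "G4")),
    nlt_edges = data.frame(first = c("G1", "G2"), second = c("G2", "G3"),
                           target = c("G4", "G5")))
  params <- grn_params(
    alpha = data.frame(source = c("G1", "G1", "G2", "G2", "G3"),
                       target = c("G2", "G3", "G3", "G4", "G4"),
                       value = c(0.03, -0.012, 0.05, 0.04, -0.012)),
    beta = data.frame(first = c("G1", "G2"), second = c("G2", "G3"),
                      target = c("G4", "G5"),
                      value = c(0.025, 0.035)),
    k = setNames(c(0.02, 0.05, 0.1, 0.15, 0.25), genes), net = net)
  x0 <- c(2, 0.3, 1, 0.5, 1.5)
  grid <- paper_time_grid()
  traj <- simulate_trajectory(params, net, x0, grid)
  stopifnot(traj$status == "ok", all(traj$values >= 0))
  list(net = net, params = params, x0 = x0,
       ds = gene_dataset(genes, grid, traj$values))
}

# GA settings for the scaled-down recovery runs
benchmark_ga_config <- function(n_restarts = 10, top_k = 1,
                                generations = 200, population = 60) {
  ga_config(generations = generations, population = population,
            n_restarts = n_restarts, top_k = top_k,
            bounds = list(alpha = c(-0.06, 0.06), beta = c(-0.06, 0.06),
                          k = c(0, 1)),
            base_seed = 5, normalize = "none")
}

# a single-gene pure-decay dataset on the standard grid
make_decay_ds <- function(k = 0.5, x0 = 1) {
  grid <- paper_time_grid()
  gene_dataset("G1", grid, matrix(x0 * exp(-k * grid), 1))
}

# iid standard-normal "null" dataset shifted positive (no structure)
make_null_ds <- function(m, M, seed) {
  set.seed(seed)
  gene_dataset(sprintf("G%02d", seq_len(m)), seq_len(M) - 1,
               matrix(abs(rnorm(m * M)) + 0.1, m))
}

# deterministic padded network over the 11 published gene names, with
# `m1` gene edges and `n1` NLT edges that are guaranteed to contain the
# given must-have edges; gene edges are oriented along the gene order so
# the subgraph is a DAG
make_named_network <- function(m1, n1, must_gene = NULL, must_nlt = NULL) {
  genes <- c("Gata1", "Gata2", "PU.1", "Runx1", "Cbfa2t3", "Ets1",
             "Notch1", "Tal1", "Ldb1", "Gfi1", "Lmo2")
  pairs <- enumerate_nlts(length(genes))
  ge <- data.frame(source = genes[pairs$first], target = genes[pairs$second])
  key <- function(s, t) paste(s, t)
  if (!is.null(must_gene)) {
    # must-have gene edges come first, possibly re-oriented rows of `ge`
    have <- key(ge$source, ge$target)
    idx <- match(key(pmin2(must_gene$source, must_gene$target, genes),
                     pmax2(must_gene$source, must_gene$target, genes)), have)
    stopifnot(!anyNA(idx))
    rest <- ge[-idx, , drop = FALSE]
    ge <- rbind(must_gene[, c("source", "target")], rest)
  }
  ge <- ge[seq_len(m1), , drop = FALSE]
  ne <- data.frame(first = genes[rep(pairs$first, length(genes))],
                   second = genes[rep(pairs$second, length(genes))],
                   target = rep(genes, each = nrow(pairs)))
  if (!is.null(must_nlt)) {
    k3 <- function(d) paste(d$first, d$second, d$target)
    idx <- match(k3(must_nlt), k3(ne))
    stopifnot(!anyNA(idx))
    ne <- rbind(must_nlt, ne[-idx, , drop = FALSE])
  }
  ne <- ne[seq_len(n1), , drop = FALSE]
  grn_network(genes, ge, ne)
}

# order a pair of gene names along the gene-panel order
pmin2 <- function(a, b, genes) ifelse(match(a, genes) < match(b, genes), a, b)
pmax2 <- function(a, b, genes) ifelse(match(a, genes) < match(b, genes), b, a)
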