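# Plain-text readers/writers: expression TSV, network edge table / SIF,
# and the parameter key-value document. All readers reject malformed input
# with line numbers rather than coercing silently.

#' Read a tab-separated expression dataset
#'
#' Expected layout: first row `gene<TAB>t1<TAB>t2...` with numeric times in
#' hours, then one row per gene: name followed by one value per time point.
#'
#' @param path file path.
#' @return a [gene_dataset()].
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop("expression file needs a header and >=1 gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  if (length(hdr) < 3 || hdr[1] != "gene")
    stop("line 1: header must start with 'gene' followed by >=2 time columns")
  times <- suppressWarnings(as.numeric(hdr[-1]))
  if (any(is.na(times)))
    stop("line 1: non-numeric time header entry: ",
         hdr[-1][which(is.na(times))[1]])
  if (any(diff(times) <= 0))
    stop("line 1: time header must be strictly increasing (monotonicity)")
  M <- length(times)
  body <- fields[-1]
  nf <- lengths(body)
  if (any(nf != M + 1L))
    stop("line ", which(nf != M + 1L)[1] + 1L, ": expected ", M + 1L,
         " fields, found ", nf[nf != M + 1L][1], " (ragged row)")
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes))
    stop("line ", which(duplicated(genes))[1] + 1L, ": duplicate gene name '",
         genes[duplicated(genes)][1], "'")
  values <- matrix(NA_real_, length(genes), M)
  for (i in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[i]][-1]))
    if (any(is.na(v)))
      stop("line ", i + 1L, ": non-numeric expression value")
    values[i, ] <- v
  }
  gene_dataset(genes, times, values)
}

#' Write a gene expression dataset as TSV
#'
#' Emits the dialect read by [read_expression()]; times and values are
#' written with full double precision so that write-then-read round-trips.
#'
#' @param ds a [gene_dataset()] (or any object with `genes`, `times`,
#'   `values` fields, e.g. a trajectory converted via [trajectory_dataset()]).
#' @param path output path.
#' @export
write_expression <- function(ds, path) {
  fmt <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
  hdr <- paste(c("gene", fmt(ds$times)), collapse = "\t")
  rows <- vapply(seq_along(ds$genes), function(i)
    paste(c(ds$genes[i], fmt(ds$values[i, ])), collapse = "\t"),
    character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Write an inferred network
#'
#' `edge_table` writes one row per edge with columns `source`, `target`,
#' `source_kind` (gene|nlt), `rank`, `p_value`, `coefficient` (blank when no
#' fitted parameters are supplied); NLT sources are labelled "geneA:geneB".
#' `sif` writes Cytoscape simple-interaction lines
#' `source regulates target`. A `#genes` comment line preserves the full
#' gene panel for lossless round-trips of the edge table.
#'
#' @param net a [grn_network()].
#' @param path output path.
#' @param format `"edge_table"` or `"sif"`.
#' @param params optional [grn_params()] supplying the coefficient column.
#' @export
write_network <- function(net, path, format = c("edge_table", "sif"),
                          params = NULL) {
  format <- match.arg(format)
  ge <- net$gene_edges
  ne <- net$nlt_edges
  nlt_src <- if (nrow(ne)) paste0(ne$first, ":", ne$second) else character()
  if (format == "sif") {
    lines <- c(
      if (nrow(ge)) paste(ge$source, "regulates", ge$target),
      if (nrow(ne)) paste(nlt_src, "regulates", ne$target))
    writeLines(lines, path)
    return(invisible(path))
  }
  coef_a <- rep(NA_real_, nrow(ge))
  coef_b <- rep(NA_real_, nrow(ne))
  if (!is.null(params)) {
    key <- function(...) paste(..., sep = "\r")
    coef_a <- params$alpha$value[match(key(ge$source, ge$target),
                                       key(params$alpha$source,
                                           params$alpha$target))]
    coef_b <- params$beta$value[match(key(ne$first, ne$second, ne$target),
                                      key(params$beta$first,
                                          params$beta$second,
                                          params$beta$target))]
  }
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 17, trim = TRUE))
  tab <- rbind(
    if (nrow(ge)) data.frame(source = ge$source, target = ge$target,
                             source_kind = "gene", rank = fmt(ge$rank),
                             p_value = fmt(ge$p_value),
                             coefficient = fmt(coef_a)),
    if (nrow(ne)) data.frame(source = nlt_src, target = ne$target,
                             source_kind = "nlt", rank = fmt(ne$rank),
                             p_value = fmt(ne$p_value),
                             coefficient = fmt(coef_b)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#genes\t", paste(net$genes, collapse = "\t")), con)
  if (length(net$isolated_nlts))
    writeLines(paste0("#isolated_nlts\t",
                      paste(net$isolated_nlts, collapse = "\t")), con)
  writeLines("source\ttarget\tsource_kind\trank\tp_value\tcoefficient", con)
  if (!is.null(tab))
    writeLines(do.call(paste, c(tab, sep = "\t")), con)
  invisible(path)
}

#' Read a network edge table written by [write_network()]
#'
#' @param path edge-table path.
#' @return a [grn_network()] (coefficients, if present, are attached as
#'   attribute `"coefficients"`).
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  genes <- NULL
  isolated <- character()
  while (length(lines) && startsWith(lines[1], "#")) {
    f <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    if (f[1] == "#genes") genes <- f[-1]
    if (f[1] == "#isolated_nlts") isolated <- f[-1]
    lines <- lines[-1]
  }
  if (is.null(genes)) stop("missing #genes header line")
  if (!length(lines) || lines[1] != "source\ttarget\tsource_kind\trank\tp_value\tcoefficient")
    stop("unrecognised edge-table header")
  body <- lines[-1]
  body <- body[nzchar(body)]
  num <- function(x) suppressWarnings(ifelse(x == "", NA_real_, as.numeric(x)))
  if (length(body)) {
    f <- strsplit(body, "\t", fixed = TRUE)
    # strsplit drops a trailing empty field (blank coefficient)
    trail <- endsWith(body, "\t")
    f[trail] <- lapply(f[trail], c, "")
    if (any(lengths(f) != 6))
      stop("ragged edge-table row at line ", which(lengths(f) != 6)[1])
    tab <- data.frame(source = vapply(f, `[[`, "", 1),
                      target = vapply(f, `[[`, "", 2),
                      source_kind = vapply(f, `[[`, "", 3),
                      rank = num(vapply(f, `[[`, "", 4)),
                      p_value = num(vapply(f, `[[`, "", 5)),
                      coefficient = num(vapply(f, `[[`, "", 6)))
  } else {
    tab <- data.frame(source = character(), target = character(),
                      source_kind = character(), rank = numeric(),
                      p_value = numeric(), coefficient = numeric())
  }
  if (!all(tab$source_kind %in% c("gene", "nlt")))
    stop("unknown source_kind value")
  g <- tab[tab$source_kind == "gene", ]
  n <- tab[tab$source_kind == "nlt", ]
  pair <- strsplit(n$source, ":", fixed = TRUE)
  ne <- data.frame(first = vapply(pair, `[[`, "", 1),
                   second = vapply(pair, function(p) p[[2]], ""),
                   target = n$target, rank = n$rank, p_value = n$p_value)
  net <- grn_network(genes,
                     data.frame(source = g$source, target = g$target,
                                rank = g$rank, p_value = g$p_value),
                     ne, isolated_nlts = isolated)
  attr(net, "coefficients") <- tab$coefficient
  net
}

#' Write model parameters as a key-value text document
#'
#' One line per coefficient: `alpha<TAB>source<TAB>target<TAB>value`,
#' `beta<TAB>first:second<TAB>target<TAB>value`, `k<TAB>gene<TAB>value`,
#' preceded by a `format_version` line.
#'
#' @param params a [grn_params()].
#' @param path output path.
#' @export
write_params <- function(params, path) {
  fmt <- function(x) format(x, digits = 17, trim = TRUE)
  lines <- c("format_version\t1",
             if (nrow(params$alpha))
               paste("alpha", params$alpha$source, params$alpha$target,
                     fmt(params$alpha$value), sep = "\t"),
             if (nrow(params$beta))
               paste("beta", paste0(params$beta$first, ":", params$beta$second),
                     params$beta$target, fmt(params$beta$value), sep = "\t"),
             paste("k", names(params$k), fmt(unname(params$k)), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameter document written by [write_params()]
#'
#' @param path input path.
#' @param net optional companion [grn_network()] for support validation.
#' @return a [grn_params()].
#' @export
read_params <- function(path, net = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (f[[1]][1] != "format_version")
    stop("line 1: missing format_version")
  if (f[[1]][2] != "1") stop("unsupported format_version ", f[[1]][2])
  kind <- vapply(f[-1], `[[`, "", 1)
  rows <- f[-1]
  pick <- function(what) rows[kind == what]
  a <- pick("alpha"); b <- pick("beta"); kk <- pick("k")
  bad <- which(!kind %in% c("alpha", "beta", "k"))
  if (length(bad)) stop("line ", bad[1] + 1L, ": unknown record kind '",
                        kind[bad[1]], "'")
  alpha <- if (length(a))
    data.frame(source = vapply(a, `[[`, "", 2),
               target = vapply(a, `[[`, "", 3),
               value = as.numeric(vapply(a, `[[`, "", 4)))
  beta <- if (length(b)) {
    pr <- strsplit(vapply(b, `[[`, "", 2), ":", fixed = TRUE)
    data.frame(first = vapply(pr, `[[`, "", 1),
               second = vapply(pr, `[[`, "", 2),
               target = vapply(b, `[[`, "", 3),
               value = as.numeric(vapply(b, `[[`, "", 4)))
  }
  k <- setNames(as.numeric(vapply(kk, `[[`, "", 3)),
                vapply(kk, `[[`, "", 2))
  grn_params(alpha, beta, k, net = net)
}

#' Write a deletion trace as CSV
#'
#' Columns `Model`, `RR` (removed regulations, "; "-separated), `SE`, `RA`,
#' `RSTD` — the layout of the edge-deletion result tables.
#'
#' @param trace a `deletion_trace` from [greedy_prune()].
#' @param path output path.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
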