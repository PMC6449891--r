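# Containers and plain-text I/O for expression matrices and networks.
#
# An expression matrix is a numeric genes x experiments matrix with unique
# rownames (gene ids) and colnames (experiment ids). Networks travel either as
# symmetric score matrices (`scored_network`) or as undirected edge lists
# (data frames with columns gene_a, gene_b, weight).

#' Construct a scored gene-gene network
#'
#' A `scored_network` wraps a square numeric score matrix over a fixed gene
#' order together with a symmetry flag and the declared score range. It is the
#' common currency for the co-membership network G, the path/correlation
#' evidence W, the extended-PPIN confidence C and the refined score R.
#'
#' @param scores square numeric matrix; rownames/colnames must agree and name
#'   the genes. Diagonal is conventionally 0 for all network uses.
#' @param symmetric logical; if `TRUE` (default) the matrix must be symmetric.
#' @param score_range declared `c(lo, hi)` range the finite entries live in.
#' @return an object of class `scored_network`.
#' @export
scored_network <- function(scores, symmetric = TRUE, score_range = range(scores)) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  if (is.null(rownames(scores))) {
    rownames(scores) <- colnames(scores) <- paste0("g", seq_len(nrow(scores)))
  }
  if (is.null(colnames(scores))) colnames(scores) <- rownames(scores)
  if (!identical(rownames(scores), colnames(scores)))
    stop("scored_network: row and column gene ids differ")
  if (anyDuplicated(rownames(scores))) stop("scored_network: duplicate gene ids")
  if (symmetric && max(abs(scores - t(scores))) > 1e-8)
    stop("scored_network: matrix declared symmetric but is not")
  structure(
    list(gene_ids = rownames(scores), scores = scores,
         symmetric = symmetric, score_range = as.numeric(score_range)),
    class = "scored_network")
}

#' @export
as.matrix.scored_network <- function(x, ...) x$scores

#' @export
print.scored_network <- function(x, ...) {
  cat(sprintf("scored_network: %d genes, %s, range [%.4g, %.4g]\n",
              length(x$gene_ids), if (x$symmetric) "symmetric" else "directed",
              x$score_range[1], x$score_range[2]))
  invisible(x)
}

#' Construct an undirected edge list
#'
#' Drops self-loops (with a message reporting how many) and collapses
#' duplicate undirected pairs keeping the maximum weight.
#'
#' @param gene_a,gene_b character vectors of endpoint gene ids.
#' @param weight numeric edge weights (recycled); defaults to 1.
#' @return data frame with columns `gene_a`, `gene_b`, `weight` and class
#'   `edge_list`; pairs are stored with `gene_a` < `gene_b` lexicographically.
#' @export
edge_list <- function(gene_a = character(), gene_b = character(), weight = 1) {
  gene_a <- as.character(gene_a); gene_b <- as.character(gene_b)
  stopifnot(length(gene_a) == length(gene_b))
  weight <- rep_len(as.numeric(weight), length(gene_a))
  self <- gene_a == gene_b
  if (any(self)) {
    message(sprintf("edge_list: dropped %d self-loop(s)", sum(self)))
    gene_a <- gene_a[!self]; gene_b <- gene_b[!self]; weight <- weight[!self]
  }
  a <- pmin(gene_a, gene_b); b <- pmax(gene_a, gene_b)
  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    w <- tapply(weight, key, max)
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
    weight <- as.numeric(w[paste(a, b, sep = "\r")])
    o <- order(a, b)
    a <- a[o]; b <- b[o]; weight <- weight[o]
  }
  structure(data.frame(gene_a = a, gene_b = b, weight = weight,
                       stringsAsFactors = FALSE),
            class = c("edge_list", "data.frame"))
}

#' Read a gene-expression matrix from TSV
#'
#' Expects a tab-separated file whose first row holds experiment labels and
#' whose first column holds gene labels. No transformation (log-scaling,
#' centering) is applied: the values are taken as-is.
#'
#' @param path file path.
#' @return numeric matrix, genes in rows, experiments in columns.
#' @export
read_expression <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("read_expression: duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) {
        bad <- which(is.na(vn))[1]
        stop(sprintf("read_expression: non-numeric value in row '%s', column '%s'",
                     genes[bad], colnames(vals)[j]))
      }
      vals[[j]] <- vn
    }
  }
  x <- as.matrix(vals)
  rownames(x) <- genes
  if (anyNA(x)) stop("read_expression: missing values")
  validate_expression(x)
  x
}

validate_expression <- function(x) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("expression matrix needs at least 2 genes and 2 experiments")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("expression matrix needs unique gene rownames")
  invisible(x)
}

#' Write a gene-expression matrix as TSV
#'
#' @param x numeric matrix with gene rownames and experiment colnames.
#' @param path output path.
#' @param header optional character vector written as leading `#` comment lines.
#' @export
write_expression <- function(x, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(c("gene", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1, function(r) paste(format(r, digits = 17, trim = TRUE,
                                               scientific = FALSE),
                                        collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read an undirected network edge list from TSV
#'
#' Accepts two or three tab-separated columns (`geneA geneB [weight]`,
#' SIF-compatible). Self-loops are dropped and duplicate undirected pairs are
#' collapsed keeping the maximum weight.
#'
#' @param path file path.
#' @param default_weight weight used when the third column is absent.
#' @return an [edge_list()].
#' @export
read_edge_list <- function(path, default_weight = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) return(edge_list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2))
    stop("read_edge_list: line with fewer than 2 columns: '",
         lines[which(ncols < 2)[1]], "'")
  a <- vapply(parts, `[[`, "", 1)
  b <- vapply(parts, `[[`, "", 2)
  w <- vapply(parts, function(p)
    if (length(p) >= 3) as.numeric(p[[3]]) else default_weight, 0)
  if (anyNA(w)) stop("read_edge_list: non-numeric weight")
  edge_list(a, b, w)
}

#' Write an edge list as TSV
#'
#' @param edges an [edge_list()] or compatible data frame.
#' @param path output path.
#' @param header optional character vector written as leading `#` comment lines.
#' @export
write_edge_list <- function(edges, path, header = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (nrow(edges)) {
    writeLines(paste(edges$gene_a, edges$gene_b,
                     format(edges$weight, digits = 17, trim = TRUE,
                            scientific = FALSE), sep = "\t"), con)
  }
  invisible(path)
}

#' Threshold a symmetric score network into an edge list
#'
#' @param net a symmetric [scored_network()].
#' @param cutoff minimum score; undirected pairs with score >= cutoff are kept,
#'   each emitted once.
#' @return an [edge_list()] whose weights are the scores.
#' @export
threshold_network <- function(net, cutoff) {
  stopifnot(inherits(net, "scored_network"), net$symmetric)
  s <- net$scores
  idx <- which(upper.tri(s) & s >= cutoff, arr.ind = TRUE)
  edge_list(net$gene_ids[idx[, 1]], net$gene_ids[idx[, 2]], s[idx])
}

#' Min-max normalize the off-diagonal scores of a network
#'
#' Affinely maps off-diagonal entries onto `[0, 1]`; the diagonal is set to 0.
#'
#' @param net a [scored_network()].
#' @return the normalized [scored_network()] with `score_range = c(0, 1)`.
#' @export
minmax_normalize <- function(net) {
  stopifnot(inherits(net, "scored_network"))
  s <- net$scores
  off <- s[row(s) != col(s)]
  lo <- min(off); hi <- max(off)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < .Machine$double.eps)
    stop("minmax_normalize: off-diagonal scores are constant; normalization undefined")
  s <- (s - lo) / (hi - lo)
  diag(s) <- 0
  scored_network(s, symmetric = net$symmetric, score_range = c(0, 1))
}

#' Restrict an edge list to a gene universe
#'
#' Matching is exact-string and case-sensitive; edges with an endpoint outside
#' `genes` are dropped with a message reporting the count.
#'
#' @param edges an [edge_list()].
#' @param genes character vector of retained gene ids.
#' @return the filtered [edge_list()].
#' @export
restrict_edges <- function(edges, genes) {
  keep <- edges$gene_a %in% genes & edges$gene_b %in% genes
  if (any(!keep))
    message(sprintf("restrict_edges: dropped %d edge(s) outside the %d-gene universe",
                    sum(!keep), length(genes)))
  structure(edges[keep, , drop = FALSE], class = c("edge_list", "data.frame"))
}

#' Convert an edge list to a symmetric adjacency/score matrix
#'
#' @param edges an [edge_list()].
#' @param genes gene order of the output matrix.
#' @param use_weights if `TRUE`, fill with edge weights; otherwise 0/1.
#' @return a symmetric [scored_network()] with zero diagonal.
#' @export
edges_to_network <- function(edges, genes, use_weights = FALSE) {
  m <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  edges <- restrict_edges(edges, genes)
  if (nrow(edges)) {
    ia <- match(edges$gene_a, genes); ib <- match(edges$gene_b, genes)
    v <- if (use_weights) edges$weight else 1
    m[cbind(ia, ib)] <- v
    m[cbind(ib, ia)] <- v
  }
  scored_network(m, symmetric = TRUE, score_range = range(m))
}

#' Read a flat key-value configuration file
#'
#' Accepts YAML when the yaml package is available, otherwise (or for `.cfg`
#' files) parses `key: value` / `key = value` lines. Values that parse as
#' numbers are returned numeric.
#'
#' @param path file path.
#' @return named list of settings.
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE))
    return(yaml::read_yaml(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = ":"))
    vn <- suppressWarnings(as.numeric(v))
    if (!is.na(vn)) vn else v
  })
  names(out) <- vapply(kv, function(p) trimws(p[[1]]), "")
  out
}
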