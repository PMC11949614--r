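#' Structural connectome objects
#'
#' A `structural_connectome` holds a nonnegative weighted region-by-region
#' matrix in which row `b`, column `a` is the connection strength directed
#' from region `b` to region `a`, together with unique node labels, a
#' per-node hemisphere tag (`"A"` or `"B"`, or `NA` for networks without a
#' hemisphere structure), and a directedness flag. Bilaterally mirrored
#' connectomes built by [mirror_bilateral()] additionally carry a `base`
#' label per node (the region acronym shared by a homologous pair).
#'
#' @param weights Square numeric matrix of nonnegative weights.
#' @param regions Character vector of unique node labels, one per row.
#' @param hemisphere Optional character vector of `"A"`/`"B"` tags.
#' @param directed Logical; if `FALSE`, `weights` must be symmetric.
#' @param base Optional character vector of per-node base region acronyms.
#'
#' @return An object of class `structural_connectome`.
#' @export
structural_connectome <- function(weights, regions, hemisphere = NULL,
                                  directed = TRUE, base = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights))
    stop("`weights` must be square")
  if (any(!is.finite(weights)))
    stop("`weights` must be finite")
  if (any(weights < 0))
    stop("`weights` must be nonnegative")
  regions <- as.character(regions)
  if (length(regions) != nrow(weights))
    stop("`regions` length must match matrix dimension")
  if (anyDuplicated(regions))
    stop("`regions` must be unique")
  if (!directed && !isTRUE(all.equal(weights, t(weights), tolerance = 1e-12)))
    stop("undirected connectome requires a symmetric matrix")
  if (!is.null(hemisphere)) {
    hemisphere <- as.character(hemisphere)
    if (length(hemisphere) != length(regions))
      stop("`hemisphere` length must match `regions`")
    if (!all(hemisphere %in% c("A", "B")))
      stop("hemisphere tags must be \"A\" or \"B\"")
  }
  if (!is.null(base) && length(base) != length(regions))
    stop("`base` length must match `regions`")
  dimnames(weights) <- list(regions, regions)
  structure(list(weights = weights, regions = regions,
                 hemisphere = hemisphere, directed = isTRUE(directed),
                 base = base),
            class = "structural_connectome")
}

#' @export
print.structural_connectome <- function(x, ...) {
  n <- length(x$regions)
  ne <- sum(x$weights > 0)
  cat(sprintf("structural_connectome: %d nodes, %d nonzero %s edges\n",
              n, ne, if (x$directed) "directed" else "undirected"))
  if (!is.null(x$hemisphere))
    cat(sprintf("  hemispheres: A=%d B=%d\n",
                sum(x$hemisphere == "A"), sum(x$hemisphere == "B")))
  invisible(x)
}

#' Build a bilaterally mirrored directed connectome
#'
#' Assembles a whole-brain connectome from one hemisphere's ipsilateral and
#' contralateral connection blocks under the assumption of bilateral
#' symmetry: every weight directed from an A-hemisphere region equals its
#' counterpart directed from the homologous B-hemisphere region. The result
#' is the block matrix `[[ipsi, contra], [contra, ipsi]]` over node order
#' (A-hemisphere labels, then B-hemisphere labels).
#'
#' @param ipsi Square nonnegative matrix of within-hemisphere weights.
#' @param contra Square nonnegative matrix of between-hemisphere weights
#'   (same region order as `ipsi`).
#' @param labels Region acronyms for one hemisphere.
#'
#' @return A directed [structural_connectome()] on `2 * length(labels)`
#'   nodes, labelled `<acronym>_A` and `<acronym>_B`.
#' @export
mirror_bilateral <- function(ipsi, contra, labels) {
  ipsi <- as.matrix(ipsi); contra <- as.matrix(contra)
  h <- length(labels)
  if (nrow(ipsi) != h || ncol(ipsi) != h ||
      nrow(contra) != h || ncol(contra) != h)
    stop("`ipsi` and `contra` must be square with one row per label")
  if (any(ipsi < 0) || any(contra < 0))
    stop("connection weights must be nonnegative")
  W <- rbind(cbind(ipsi, contra), cbind(contra, ipsi))
  structural_connectome(
    W,
    regions = c(paste0(labels, "_A"), paste0(labels, "_B")),
    hemisphere = rep(c("A", "B"), each = h),
    directed = TRUE,
    base = rep(as.character(labels), 2))
}

#' Collapse a directed connectome to an undirected one
#'
#' The undirected weight between a pair of regions is the sum of the two
#' directed weights between them.
#'
#' @param sc A directed [structural_connectome()].
#' @return An undirected `structural_connectome` with weights
#'   `W + t(W)`.
#' @export
to_undirected <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  if (!sc$directed) stop("connectome is already undirected")
  structural_connectome(sc$weights + t(sc$weights), sc$regions,
                        hemisphere = sc$hemisphere, directed = FALSE,
                        base = sc$base)
}

#' Normalize connectome weights
#'
#' Zeroes the self-connections on the main diagonal, then rescales all
#' weights so the maximum edge strength in the network is exactly 1. An
#' all-zero matrix is returned unchanged with a warning.
#'
#' @param sc A [structural_connectome()].
#' @return The normalized `structural_connectome`.
#' @export
normalize_connectome <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  W <- sc$weights
  diag(W) <- 0
  mx <- max(W)
  if (mx == 0) {
    warning("all-zero connectome; normalization skipped")
  } else {
    W <- W / mx
  }
  structural_connectome(W, sc$regions, hemisphere = sc$hemisphere,
                        directed = sc$directed, base = sc$base)
}

#' Reduce a connectome to a region subset
#'
#' Extracts the submatrix on the kept regions, preserving the original
#' relative node order. Weights are deliberately not re-normalized, so the
#' reduced and full networks share the same edge scale.
#'
#' @param sc A [structural_connectome()].
#' @param keep Character vector of node labels to retain.
#' @return The reduced `structural_connectome`.
#' @export
reduce_to_regions <- function(sc, keep) {
  stopifnot(inherits(sc, "structural_connectome"))
  unknown <- setdiff(keep, sc$regions)
  if (length(unknown))
    stop("unknown region label(s): ", paste(unknown, collapse = ", "))
  idx <- which(sc$regions %in% keep)
  structural_connectome(sc$weights[idx, idx, drop = FALSE],
                        sc$regions[idx],
                        hemisphere = if (!is.null(sc$hemisphere)) sc$hemisphere[idx],
                        directed = sc$directed,
                        base = if (!is.null(sc$base)) sc$base[idx])
}

#' Degree-preserving randomization of a directed connectome
#'
#' Maslov–Sneppen edge-swap rewiring for weighted directed networks: pairs
#' of directed edges (b1 -> a1), (b2 -> a2) are rewired to (b1 -> a2),
#' (b2 -> a1) whenever the swap creates neither a self-loop nor a duplicate
#' edge; each weight travels with its source endpoint. Every edge is swapped
#' `swaps_per_edge` times on average, so in- and out-degree sequences and
#' the global multiset of edge weights are preserved exactly while the
#' placement of edges is randomized.
#'
#' @param sc A directed [structural_connectome()].
#' @param swaps_per_edge Average number of swaps attempted per edge.
#' @param seed Integer seed for reproducibility.
#' @return The rewired `structural_connectome`.
#' @export
randomize_directed <- function(sc, swaps_per_edge = 20, seed) {
  stopifnot(inherits(sc, "structural_connectome"))
  if (!sc$directed) stop("randomize_directed requires a directed connectome")
  if (swaps_per_edge < 1) stop("`swaps_per_edge` must be >= 1")
  W <- sc$weights
  e <- which(W > 0, arr.ind = TRUE)  # columns: source row, target col
  m <- nrow(e)
  if (m < 2) stop("too few edges to swap")
  src <- e[, 1]; tgt <- e[, 2]
  wts <- W[e]
  set.seed(as.integer(seed))
  n_attempts <- ceiling(swaps_per_edge * m)
  # adjacency presence for duplicate checks, updated as edges move
  n <- nrow(W)
  key <- function(s, t) (s - 1) * n + t
  present <- new.env(hash = TRUE, size = m * 2L)
  for (k in seq_len(m)) assign(as.character(key(src[k], tgt[k])), TRUE, envir = present)
  has_edge <- function(s, t) !is.null(present[[as.character(key(s, t))]])
  picks <- matrix(sample.int(m, 2L * n_attempts, replace = TRUE), ncol = 2L)
  for (it in seq_len(n_attempts)) {
    i <- picks[it, 1]; j <- picks[it, 2]
    if (i == j) next
    s1 <- src[i]; t1 <- tgt[i]; s2 <- src[j]; t2 <- tgt[j]
    if (s1 == t2 || s2 == t1) next            # would create self-loop
    if (t1 == t2) next                        # no-op / duplicate risk
    if (has_edge(s1, t2) || has_edge(s2, t1)) next
    rm(list = c(as.character(key(s1, t1)), as.character(key(s2, t2))),
       envir = present)
    tgt[i] <- t2; tgt[j] <- t1
    assign(as.character(key(s1, t2)), TRUE, envir = present)
    assign(as.character(key(s2, t1)), TRUE, envir = present)
  }
  W2 <- matrix(0, n, n, dimnames = dimnames(W))
  W2[cbind(src, tgt)] <- wts
  structural_connectome(W2, sc$regions, hemisphere = sc$hemisphere,
                        directed = TRUE, base = sc$base)
}

#' Weighted global efficiency
#'
#' Mean over all ordered node pairs (a != b) of the inverse weighted
#' shortest-path length, where the length of each edge is the inverse of
#' its connection strength. Unreachable pairs contribute zero; a network
#' with fewer than two nodes has efficiency 0.
#'
#' @param sc A [structural_connectome()] (directed paths are respected for
#'   directed networks).
#' @return A nonnegative scalar.
#' @export
global_efficiency <- function(sc) {
  stopifnot(inherits(sc, "structural_connectome"))
  W <- sc$weights
  n <- nrow(W)
  if (n < 2) return(0)
  g <- igraph::graph_from_adjacency_matrix(
    W, mode = if (sc$directed) "directed" else "undirected",
    weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) return(0)
  d <- igraph::distances(g, mode = "out",
                         weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

#' Read a connectome from delimited text
#'
#' Expects a square matrix file with a header row and first column of
#' region labels, and optionally a companion label table with columns
#' `label`, `hemisphere` and (optionally) `base`.
#'
#' @param matrix_file Path to the CSV/TSV weight matrix.
#' @param labels_file Optional path to the label table.
#' @param directed Directedness of the stored network.
#' @param sep Field separator.
#' @return A [structural_connectome()].
#' @export
read_connectome <- function(matrix_file, labels_file = NULL, directed = TRUE,
                            sep = ",") {
  m <- utils::read.table(matrix_file, header = TRUE, sep = sep,
                         row.names = 1, check.names = FALSE)
  W <- as.matrix(m)
  hemisphere <- NULL; base <- NULL
  regions <- rownames(W)
  if (!is.null(labels_file)) {
    lab <- utils::read.table(labels_file, header = TRUE, sep = sep,
                             check.names = FALSE, stringsAsFactors = FALSE)
    lab <- lab[match(regions, lab$label), , drop = FALSE]
    if ("hemisphere" %in% names(lab)) hemisphere <- lab$hemisphere
    if ("base" %in% names(lab)) base <- lab$base
  }
  structural_connectome(W, regions, hemisphere = hemisphere,
                        directed = directed, base = base)
}

#' Write a connectome to delimited text plus JSON metadata
#'
#' @param sc A [structural_connectome()].
#' @param matrix_file Output path for the weight matrix CSV.
#' @param labels_file Optional output path for the label table CSV.
#' @param meta_file Optional output path for JSON metadata (directedness,
#'   size, normalization state).
#' @return Invisibly, `sc`.
#' @export
write_connectome <- function(sc, matrix_file, labels_file = NULL,
                             meta_file = NULL) {
  stopifnot(inherits(sc, "structural_connectome"))
  df <- data.frame(label = sc$regions, sc$weights, check.names = FALSE)
  utils::write.table(df, matrix_file, sep = ",", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(labels_file)) {
    lab <- data.frame(label = sc$regions,
                      hemisphere = if (is.null(sc$hemisphere)) NA else sc$hemisphere,
                      base = if (is.null(sc$base)) NA else sc$base)
    utils::write.table(lab, labels_file, sep = ",", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(meta_file)) {
    offdiag <- sc$weights[row(sc$weights) != col(sc$weights)]
    meta <- list(n_nodes = length(sc$regions), directed = sc$directed,
                 max_weight = max(sc$weights),
                 normalized = isTRUE(all.equal(max(offdiag), 1)))
    jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA)
  }
  invisible(sc)
}
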