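#' Build a social multiplex network
#'
#' Constructs `n_layers` independent scale-free (preferential-attachment)
#' layers over a shared node set. Layers model distinct social channels
#' (e.g. workplace and friendship ties) between the same individuals; each
#' node is additionally coupled to its own replica in every other layer with
#' weight `coupling_weight` when the supra-adjacency matrix is formed (see
#' [communicability()]).
#'
#' @param n_nodes Number of nodes `N` shared by all layers.
#' @param n_layers Number of layers `M` (>= 1).
#' @param attachment Preferential-attachment parameter `m`: edges brought in
#'   by each new node. `attachment = 1` yields a tree on every layer.
#' @param coupling_weight Nonnegative weight of the inter-layer links joining
#'   a node to its replicas.
#' @param seed Optional integer seed; the same seed reproduces the same edge
#'   sets exactly.
#' @return An object of class `multiplex`: a list with `n_nodes`, `n_layers`,
#'   `coupling_weight`, `layers` (list of symmetric 0/1 adjacency matrices
#'   with zero diagonal), `nbrs` (per-layer adjacency lists) and `homophily`
#'   (per-node attribute vector, `NULL` until [assign_homophily()] is called).
#' @seealso [assign_homophily()], [communicability()], [delta_matrix()]
#' @examples
#' mx <- build_multiplex(20, n_layers = 2, seed = 1)
#' mx
#' @export
build_multiplex <- function(n_nodes, n_layers = 2, attachment = 2,
                            coupling_weight = 1, seed = NULL) {
  if (n_layers < 1) stop("n_layers must be >= 1", call. = FALSE)
  if (attachment < 1 || n_nodes <= attachment)
    stop("need n_nodes > attachment >= 1", call. = FALSE)
  if (coupling_weight < 0) stop("coupling_weight must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  layers <- vector("list", n_layers)
  for (a in seq_len(n_layers)) {
    g <- igraph::sample_pa(n_nodes, m = attachment, directed = FALSE)
    A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = TRUE))
    A[A > 1] <- 1            # collapse multi-edges from the PA process
    diag(A) <- 0
    storage.mode(A) <- "double"
    layers[[a]] <- A
  }
  mx <- structure(list(
    n_nodes = as.integer(n_nodes),
    n_layers = as.integer(n_layers),
    attachment = as.integer(attachment),
    coupling_weight = coupling_weight,
    layers = layers,
    nbrs = lapply(layers, function(A) apply(A > 0, 1L, which, simplify = FALSE)),
    homophily = NULL
  ), class = "multiplex")
  mx
}

#' @export
print.multiplex <- function(x, ...) {
  edges <- vapply(x$layers, function(A) sum(A) / 2, numeric(1))
  cat("Social multiplex:", x$n_nodes, "nodes x", x$n_layers, "layers\n")
  cat("  edges per layer:", paste(edges, collapse = ", "),
      "| inter-layer coupling:", x$coupling_weight, "\n")
  if (!is.null(x$homophily))
    cat("  homophily attribute: mean", round(mean(x$homophily), 3),
        "sd", round(stats::sd(x$homophily), 3), "\n")
  invisible(x)
}

#' Draw per-node homophily attributes
#'
#' Assigns each node an i.i.d. Normal(`mean`, `sigma`) attribute `h_i`.
#' A small `sigma` makes the population homogeneous (all pairwise couplings
#' high); a large `sigma` spreads attitudes out and weakens imitation between
#' dissimilar nodes.
#'
#' @param multiplex A [build_multiplex()] object.
#' @param mean,sigma Mean and standard deviation of the attribute
#'   distribution; `sigma` must be > 0.
#' @param seed Optional integer seed.
#' @return The multiplex with `$homophily` filled in.
#' @export
assign_homophily <- function(multiplex, mean = 5, sigma = 1, seed = NULL) {
  stopifnot(inherits(multiplex, "multiplex"))
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  multiplex$homophily <- stats::rnorm(multiplex$n_nodes, mean, sigma)
  multiplex
}

#' Supra-adjacency matrix of a multiplex
#'
#' Block matrix with layer adjacencies on the diagonal blocks and
#' `coupling_weight * I` on every off-diagonal block (each node linked to its
#' replica on every other layer).
#'
#' @param multiplex A `multiplex` object.
#' @return A dense `(N*M) x (N*M)` symmetric matrix; node `i` of layer `a`
#'   sits at row `(a-1)*N + i`.
#' @export
supra_adjacency <- function(multiplex) {
  N <- multiplex$n_nodes; M <- multiplex$n_layers
  w <- multiplex$coupling_weight
  S <- matrix(0, N * M, N * M)
  for (a in seq_len(M)) {
    ia <- (a - 1L) * N + seq_len(N)
    S[ia, ia] <- multiplex$layers[[a]]
    if (M > 1) for (b in seq_len(M)) if (b != a) {
      ib <- (b - 1L) * N + seq_len(N)
      S[cbind(ia, ib)] <- w
    }
  }
  S
}

#' Communicability matrix of a multiplex
#'
#' The matrix exponential of the supra-adjacency matrix. Entry
#' `[G_ab]_ij` weighs all walks joining node `i` on layer `a` to node `j` on
#' layer `b` (walks of length `k` damped by `1/k!`), i.e. the number of
#' routes the two have to communicate. It feeds the cross-layer term of the
#' strategy-update rule (see [eta()]).
#'
#' @param multiplex A `multiplex` object.
#' @return Object of class `communicability`: list with the full `(NM) x (NM)`
#'   matrix (`$full`), `n_nodes` and `n_layers`. Use [comm_block()] to
#'   extract the `N x N` block for a layer pair.
#' @examples
#' mx <- build_multiplex(10, 2, seed = 1)
#' G <- communicability(mx)
#' dim(comm_block(G, 1, 2))
#' @export
communicability <- function(multiplex) {
  S <- supra_adjacency(multiplex)
  E <- as.matrix(Matrix::expm(Matrix::Matrix(S)))
  E <- (E + t(E)) / 2    # symmetrize roundoff
  structure(list(full = E,
                 n_nodes = multiplex$n_nodes,
                 n_layers = multiplex$n_layers),
            class = "communicability")
}

#' Extract one layer-pair block of a communicability matrix
#'
#' @param G A [communicability()] object.
#' @param alpha,beta Layer indices.
#' @return The `N x N` block `G_ab`.
#' @export
comm_block <- function(G, alpha, beta) {
  N <- G$n_nodes
  G$full[(alpha - 1L) * N + seq_len(N), (beta - 1L) * N + seq_len(N),
         drop = FALSE]
}

#' @export
print.communicability <- function(x, ...) {
  cat("Communicability matrix:", x$n_layers, "x", x$n_layers,
      "blocks of", x$n_nodes, "x", x$n_nodes, "\n")
  invisible(x)
}

#' Pairwise homophily couplings
#'
#' Converts attribute differences into a similarity `delta_ij` in
#' `[floor, 1]`: `delta_ij = max(floor, 1 - |h_i - h_j| / scale)`. By default
#' `scale` is the largest pairwise difference in the population, so the most
#' dissimilar pair sits exactly at the floor. A fixed numeric `scale` makes
#' couplings comparable across populations with different attribute spreads
#' (needed when contrasting narrow and wide homophily regimes, where the
#' relative normalization would cancel the spread out). The positive floor
#' keeps the Fermi denominator away from zero. If all attributes are equal,
#' every coupling is 1.
#'
#' @param h Numeric vector of node attributes.
#' @param floor Lower bound of the coupling, in (0, 1).
#' @param scale Normalizing dissimilarity; `NULL` (default) uses
#'   `max |h_i - h_j|` over the population.
#' @return Symmetric `N x N` matrix with unit diagonal, entries in
#'   `[floor, 1]`.
#' @examples
#' delta_matrix(c(0, 1, 2))    # 0.5 for adjacent pairs, floor for (1,3)
#' @export
delta_matrix <- function(h, floor = 0.05, scale = NULL) {
  if (floor <= 0 || floor >= 1) stop("floor must be in (0,1)", call. = FALSE)
  D <- abs(outer(h, h, "-"))
  mx <- if (is.null(scale)) max(D) else scale
  if (mx <= 0) {
    delta <- matrix(1, length(h), length(h))
  } else {
    delta <- pmax(1 - D / mx, floor)
  }
  diag(delta) <- 1
  delta
}

#' Homophily coupling of a single pair
#'
#' Scalar form of [delta_matrix()]; `scale` must be supplied here since a
#' single pair carries no population context.
#'
#' @param h_i,h_j Attribute values.
#' @param floor Lower bound in (0, 1).
#' @param scale Normalizing dissimilarity (> 0).
#' @return Scalar coupling in `[floor, 1]`.
#' @export
homophily_coupling <- function(h_i, h_j, floor = 0.05, scale) {
  if (floor <= 0 || floor >= 1) stop("floor must be in (0,1)", call. = FALSE)
  if (missing(scale) || scale <= 0) stop("scale must be > 0", call. = FALSE)
  max(floor, 1 - abs(h_i - h_j) / scale)
}

#' Write / read multiplex edge lists
#'
#' Tab-separated columns `node_u`, `node_v`, `layer` (undirected edges listed
#' once with `node_u < node_v`). Homophily attributes travel separately as a
#' two-column CSV (`node`, `h`).
#'
#' @param multiplex A `multiplex` object.
#' @param path Output file.
#' @export
write_multiplex_edges <- function(multiplex, path) {
  rows <- do.call(rbind, lapply(seq_len(multiplex$n_layers), function(a) {
    idx <- which(multiplex$layers[[a]] > 0, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    data.frame(node_u = idx[, 1], node_v = idx[, 2], layer = a)
  }))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_multiplex_edges
#' @param n_nodes,coupling_weight Passed through to the reconstructed object
#'   (the edge list does not carry them).
#' @export
read_multiplex_edges <- function(path, n_nodes, coupling_weight = 1) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  M <- max(df$layer)
  layers <- lapply(seq_len(M), function(a) {
    A <- matrix(0, n_nodes, n_nodes)
    e <- df[df$layer == a, , drop = FALSE]
    A[cbind(e$node_u, e$node_v)] <- 1
    A[cbind(e$node_v, e$node_u)] <- 1
    A
  })
  structure(list(n_nodes = as.integer(n_nodes), n_layers = as.integer(M),
                 attachment = NA_integer_, coupling_weight = coupling_weight,
                 layers = layers,
                 nbrs = lapply(layers, function(A)
                   apply(A > 0, 1L, which, simplify = FALSE)),
                 homophily = NULL),
            class = "multiplex")
}

#' @rdname write_multiplex_edges
#' @export
write_homophily <- function(multiplex, path) {
  stopifnot(!is.null(multiplex$homophily))
  utils::write.csv(data.frame(node = seq_len(multiplex$n_nodes),
                              h = multiplex$homophily),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_multiplex_edges
#' @export
read_homophily <- function(multiplex, path) {
  df <- utils::read.csv(path)
  multiplex$homophily <- df$h[order(df$node)]
  multiplex
}
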