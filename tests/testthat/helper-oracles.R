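# Independent oracles used by the unit and acceptance tests. These share no
# code with the package's implementations.

# --- truncated-series communicability -------------------------------------
# exp(A) via 30 power-series terms
series_expm <- function(A, terms = 30) {
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# --- vertex-enumeration LP oracle -----------------------------------------
# max obj'v  s.t.  Aeq v = 0, Age v >= bge, lb <= v <= ub, by enumerating
# basic solutions: every choice of (n - m_eq) active inequality constraints
# (variable bounds and Age rows) completing the equality system. Exponential;
# only for tiny models.
enum_lp <- function(obj, Aeq, lb, ub, Age = NULL, bge = NULL, tol = 1e-7) {
  n <- length(obj)
  m_eq <- nrow(Aeq)
  # inequality constraints as rows a'v = b when active
  rows <- list()
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    if (is.finite(lb[i])) rows[[length(rows) + 1]] <- list(a = e, b = lb[i])
    if (is.finite(ub[i])) rows[[length(rows) + 1]] <- list(a = e, b = ub[i])
  }
  if (!is.null(Age)) for (i in seq_len(nrow(Age)))
    rows[[length(rows) + 1]] <- list(a = Age[i, ], b = bge[i])
  k <- n - m_eq
  if (k < 0) stop("overdetermined")
  best <- -Inf; best_v <- NULL
  feasible <- function(v) {
    all(abs(Aeq %*% v) < tol) && all(v >= lb - tol) && all(v <= ub + tol) &&
      (is.null(Age) || all(Age %*% v >= bge - tol))
  }
  idx <- utils::combn(length(rows), k)
  for (cc in seq_len(ncol(idx))) {
    sel <- rows[idx[, cc]]
    M <- rbind(Aeq, do.call(rbind, lapply(sel, `[[`, "a")))
    rhs <- c(rep(0, m_eq), vapply(sel, `[[`, numeric(1), "b"))
    v <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(v) || !feasible(v)) next
    val <- sum(obj * v)
    if (val > best + 1e-12) { best <- val; best_v <- v }
  }
  if (is.null(best_v)) return(list(status = "infeasible"))
  list(status = "optimal", value = best, x = best_v)
}

# lexicographic FBA by repeated enum_lp (independent route)
enum_lex_fba <- function(model, tolerance = 1e-6, min_biomass = 0.01) {
  rx <- model$reactions
  lb <- rx$lb; ub <- rx$ub
  is_bio <- rx$id %in% model$biomass_objectives
  lb[is_bio] <- pmax(lb[is_bio], min_biomass)
  Age <- NULL; bge <- NULL
  opts <- numeric(0)
  for (k in seq_along(model$biomass_objectives)) {
    obj <- as.numeric(rx$id == model$biomass_objectives[k])
    sol <- enum_lp(obj, model$stoich, lb, ub, Age, bge)
    if (sol$status != "optimal") stop("oracle infeasible at level ", k)
    opts[k] <- sol$value
    Age <- rbind(Age, obj); bge <- c(bge, sol$value - tolerance)
  }
  opts
}

# --- greedy minimum-variance (Ward) agglomeration oracle -------------------
# returns the sequence of merged partitions (each a list of sorted member
# vectors) from exhaustive search over cluster pairs
ward_oracle <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  sse_increase <- function(a, b) {
    na <- length(a); nb <- length(b)
    ma <- colMeans(X[a, , drop = FALSE]); mb <- colMeans(X[b, , drop = FALSE])
    na * nb / (na + nb) * sum((ma - mb)^2)
  }
  merges <- list()
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) if (i < j) {
      d <- sse_increase(clusters[[i]], clusters[[j]])
      if (d < best - 1e-12) { best <- d; bi <- i; bj <- j }
    }
    merged <- sort(c(clusters[[bi]], clusters[[bj]]))
    clusters <- c(clusters[-c(bi, bj)], list(merged))
    merges[[length(merges) + 1]] <- lapply(clusters, sort)
  }
  merges
}

# partition sequence from an hclust object, same format as ward_oracle
hclust_partitions <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1)
  get_members <- function(k) {
    if (k < 0) return(-k)
    members[[k]]
  }
  out <- vector("list", n - 1)
  active <- lapply(seq_len(n), identity)    # singleton clusters keyed by node
  for (s in seq_len(n - 1)) {
    a <- get_members(hc$merge[s, 1]); b <- get_members(hc$merge[s, 2])
    members[[s]] <- sort(c(a, b))
    drop <- vapply(active, function(cl) all(cl %in% members[[s]]), logical(1))
    active <- c(active[!drop], list(members[[s]]))
    out[[s]] <- lapply(active, sort)
  }
  out
}

# canonical form for comparing partitions irrespective of cluster order
canon <- function(partition)
  paste(sort(vapply(partition, function(x) paste(x, collapse = ","),
                    character(1))), collapse = "|")

# --- small network fixtures ------------------------------------------------
complete_multiplex <- function(N, M = 1, coupling_weight = 0) {
  A <- matrix(1, N, N); diag(A) <- 0
  layers <- rep(list(A), M)
  structure(list(n_nodes = as.integer(N), n_layers = as.integer(M),
                 attachment = NA_integer_, coupling_weight = coupling_weight,
                 layers = layers,
                 nbrs = lapply(layers, function(A)
                   apply(A > 0, 1L, which, simplify = FALSE)),
                 homophily = NULL),
            class = "multiplex")
}

empty_multiplex <- function(N, M, coupling_weight = 0) {
  A <- matrix(0, N, N)
  layers <- rep(list(A), M)
  structure(list(n_nodes = as.integer(N), n_layers = as.integer(M),
                 attachment = NA_integer_, coupling_weight = coupling_weight,
                 layers = layers,
                 nbrs = lapply(layers, function(A)
                   apply(A > 0, 1L, which, simplify = FALSE)),
                 homophily = NULL),
            class = "multiplex")
}

# minimal single-species model with one linear route:
#   sugar_e -(EX)-> uptake u, yield y to biomass; used for hand-checkable LPs
single_route_model <- function(u = 2, y = 0.5) {
  mets <- data.frame(id = c("sugar_e", "c_sp1"),
                     compartment = c("e", "sp1"),
                     external = c(TRUE, FALSE))
  rxns <- data.frame(id = c("EX_sugar", "UPT_sugar_sp1", "BIO_sp1"),
                     species = c(NA, "sp1", "sp1"),
                     subsystem = c("Exchange", "Sugar transport", "Biomass"),
                     lb = c(-u, 0, 0), ub = c(1000, 1000, 1000))
  S <- matrix(0, 2, 3, dimnames = list(mets$id, rxns$id))
  S["sugar_e", "EX_sugar"] <- -1
  S["sugar_e", "UPT_sugar_sp1"] <- -1
  S["c_sp1", "UPT_sugar_sp1"] <- 1
  S["c_sp1", "BIO_sp1"] <- -1 / y
  community_model(species = "sp1", metabolites = mets, reactions = rxns,
                  stoich = S, biomass_objectives = "BIO_sp1",
                  atp_synthase_ids = c(sp1 = "UPT_sugar_sp1"),
                  exchange_groups = list(sugar = "EX_sugar"))
}

# two species competing for one substrate; priority 1 takes it all
two_species_competition <- function(u = 1, y1 = 1, y2 = 0.8) {
  mets <- data.frame(id = c("sugar_e", "c_sp1", "c_sp2"),
                     compartment = c("e", "sp1", "sp2"),
                     external = c(TRUE, FALSE, FALSE))
  rxns <- data.frame(
    id = c("EX_sugar", "UPT_sp1", "BIO_sp1", "UPT_sp2", "BIO_sp2"),
    species = c(NA, "sp1", "sp1", "sp2", "sp2"),
    subsystem = c("Exchange", "Sugar transport", "Biomass",
                  "Sugar transport", "Biomass"),
    lb = c(-u, 0, 0, 0, 0), ub = rep(1000, 5))
  S <- matrix(0, 3, 5, dimnames = list(mets$id, rxns$id))
  S["sugar_e", "EX_sugar"] <- -1
  S["sugar_e", "UPT_sp1"] <- -1; S["c_sp1", "UPT_sp1"] <- y1
  S["c_sp1", "BIO_sp1"] <- -1
  S["sugar_e", "UPT_sp2"] <- -1; S["c_sp2", "UPT_sp2"] <- y2
  S["c_sp2", "BIO_sp2"] <- -1
  community_model(species = c("sp1", "sp2"), metabolites = mets,
                  reactions = rxns, stoich = S,
                  biomass_objectives = c("BIO_sp1", "BIO_sp2"),
                  atp_synthase_ids = c(sp1 = "UPT_sp1", sp2 = "UPT_sp2"),
                  exchange_groups = list(sugar = "EX_sugar"))
}
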