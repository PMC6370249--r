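#' Snowdrift game parameters
#'
#' Bundles the payoff and update-rule constants. `b` is the benefit of the
#' common task being done, `c` (< `b`) the cost of doing it; cooperators who
#' meet split the cost. `K` is the selection intensity of the Fermi rule
#' (small `K` = near-deterministic imitation of the better-off neighbor).
#' `eta_*` and `psi_*` bound the cross-layer and psychological-bias
#' estimators away from 0 so the dynamics never freeze.
#'
#' @param b,c Benefit and cost, `b > c > 0`.
#' @param K Selection intensity, > 0.
#' @param eta_max,eta_min Range of the cross-layer estimator, default (1, 0.1).
#' @param psi_max,psi_min Range of the bias estimator, default (1, 0.1).
#' @return Object of class `game_params`.
#' @export
game_params <- function(b = 1, c = 0.8, K = 0.1,
                        eta_max = 1, eta_min = 0.1,
                        psi_max = 1, psi_min = 0.1) {
  if (!(b > c && c > 0)) stop("need b > c > 0", call. = FALSE)
  if (K <= 0) stop("K must be > 0", call. = FALSE)
  for (rng in list(c(eta_min, eta_max), c(psi_min, psi_max)))
    if (!(rng[1] > 0 && rng[1] < rng[2] && rng[2] <= 1))
      stop("estimator limits need 0 < min < max <= 1", call. = FALSE)
  structure(list(b = b, c = c, K = K,
                 eta_max = eta_max, eta_min = eta_min,
                 psi_max = psi_max, psi_min = psi_min),
            class = "game_params")
}

#' @export
print.game_params <- function(x, ...) {
  cat(sprintf("Snowdrift game: b = %g, c = %g, K = %g\n", x$b, x$c, x$K))
  cat(sprintf("  eta in [%g, %g], psi in [%g, %g]\n",
              x$eta_min, x$eta_max, x$psi_min, x$psi_max))
  cat(sprintf("  mixed equilibrium (well-mixed): rho* = %g\n",
              1 - x$c / (2 * x$b - x$c)))
  invisible(x)
}

# strategies are stored as logical/0-1 vectors: 1 = cooperate, 0 = defect
as_strategy <- function(s) {
  if (is.character(s)) s <- s %in% c("C", "c", "cooperate")
  as.numeric(s)
}

#' Pairwise snowdrift payoff
#'
#' Payoff to the first player: CC -> `b - c/2`, CD -> `b - c`, DC -> `b`,
#' DD -> 0. Vectorized.
#'
#' @param s_i,s_j Strategies: `"C"`/`"D"` or 1/0.
#' @param params A [game_params()] object.
#' @return Numeric payoff(s) to `s_i`.
#' @examples
#' p <- game_params(b = 1, c = 0.8)
#' pair_payoff("C", "C", p)  # 0.6
#' pair_payoff("D", "C", p)  # 1
#' @export
pair_payoff <- function(s_i, s_j, params) {
  si <- as_strategy(s_i); sj <- as_strategy(s_j)
  b <- params$b; c <- params$c
  # C vs C: b - c/2 ; C vs D: b - c ; D vs C: b ; D vs D: 0
  si * (sj * (b - c / 2) + (1 - sj) * (b - c)) + (1 - si) * sj * b
}

#' Accrue a node's payoff and bias counters on one layer
#'
#' The node plays one round against every neighbor on layer `alpha` and sums
#' the pairwise payoffs. Each interaction also yields a micro-affirmation
#' (the opponent cooperated: the payoff came from the "Cooperate" column of
#' the payoff matrix) or a micro-inequity (the opponent defected).
#'
#' @param node Node index.
#' @param alpha Layer index.
#' @param multiplex A `multiplex` object.
#' @param strategies 0/1 vector of current strategies (1 = cooperate).
#' @param params A [game_params()] object.
#' @return List with `payoff`, `ma_inc`, `mi_inc` (counter increments).
#' @export
accrue_payoff_and_bias <- function(node, alpha, multiplex, strategies, params) {
  nb <- multiplex$nbrs[[alpha]][[node]]
  if (length(nb) == 0L)
    return(list(payoff = 0, ma_inc = 0, mi_inc = 0))
  n_coop <- sum(strategies[nb])
  s <- strategies[node]
  payoff <- n_coop * pair_payoff(s, 1, params) +
    (length(nb) - n_coop) * pair_payoff(s, 0, params)
  list(payoff = payoff, ma_inc = n_coop, mi_inc = length(nb) - n_coop)
}

#' Cross-layer strategy-consistency estimator
#'
#' `eta_i = 1 - (eta_max - eta_min) * m_same / m_all`, where `m_same` is the
#' communicability mass between node `i` on layer `alpha` and the nodes of
#' layer `beta` sharing `i`'s strategy, and `m_all` the mass to all nodes of
#' layer `beta`. A node whose strategy is echoed everywhere on the other
#' layer has little freedom left to switch (`eta = eta_min`); one echoed
#' nowhere is maximally free (`eta = 1`). Node `i`'s own replica on `beta` is
#' excluded from both sums (it trivially shares the strategy). A zero
#' denominator returns 1.
#'
#' @param node Node index.
#' @param alpha Layer the node is playing on.
#' @param beta Layer supplying cross-layer information.
#' @param strategies 0/1 strategy vector (shared across layers).
#' @param G A [communicability()] object.
#' @param params A [game_params()] object.
#' @return Scalar in `[eta_min, 1]`.
#' @export
eta <- function(node, alpha, beta, strategies, G, params) {
  gb <- comm_block(G, alpha, beta)[node, ]
  gb[node] <- 0
  den <- sum(gb)
  if (den <= 0) return(1)
  same <- sum(gb[strategies == strategies[node]]) - 0  # node already zeroed
  1 - (params$eta_max - params$eta_min) * same / den
}

#' Micro-affirmation / micro-inequity bias estimator
#'
#' With `r = MI / (MA + MI)`, `psi = 1 - (psi_max - psi_min) * (1 - r)`.
#' All-affirmation experience pins the node to its strategy
#' (`psi = psi_min`); all-inequity experience pushes it to change
#' (`psi = 1`). With no interactions yet, the node is taken as satisfied
#' (`psi = psi_min`).
#'
#' @param ma,mi Nonnegative counter totals.
#' @param params A [game_params()] object.
#' @return Scalar in `[psi_min, psi_max]`. Vectorized over `ma`, `mi`.
#' @export
psi <- function(ma, mi, params) {
  if (any(ma < 0) || any(mi < 0)) stop("counters must be >= 0", call. = FALSE)
  tot <- ma + mi
  r <- ifelse(tot > 0, mi / tot, 0)
  ifelse(tot > 0,
         1 - (params$psi_max - params$psi_min) * (1 - r),
         params$psi_min)
}

#' Fermi strategy-adoption probability
#'
#' `W = eta_i * psi_i / (1 + exp((P_i - P_j) / (theta_ij * delta_ij * K)))`:
#' node `i` adopts `j`'s strategy with a logistic probability of the payoff
#' difference, with the effective selection temperature rescaled by the gut
#' similarity `theta_ij` and homophily coupling `delta_ij` (similar pairs
#' imitate more readily), and damped by the estimators `eta_i`, `psi_i`.
#'
#' @param P_i,P_j Accrued payoffs of the focal node and its model neighbor.
#' @param theta_ij,delta_ij Similarity factors in (0, 1].
#' @param params A [game_params()] object.
#' @param eta_i,psi_i Estimator values (default 1).
#' @return Probability in `[0, eta_i * psi_i]`.
#' @examples
#' fermi_adoption_prob(0, 1, 1, 1, game_params(K = 1))  # 1/(1+e^-1)
#' @export
fermi_adoption_prob <- function(P_i, P_j, theta_ij, delta_ij, params,
                                eta_i = 1, psi_i = 1) {
  tau <- theta_ij * delta_ij * params$K
  if (any(tau <= 0)) stop("theta, delta and K must be > 0", call. = FALSE)
  eta_i * psi_i * stats::plogis((P_j - P_i) / tau)
}

#' Game state constructor
#'
#' @param n_nodes Number of agents.
#' @param init_coop_fraction Probability each node starts as a cooperator.
#' @param seed Optional seed.
#' @return List with `strategies` (0/1), `ma`, `mi` counters and an empty
#'   `coop_history` matrix (rounds x nodes).
#' @export
game_state <- function(n_nodes, init_coop_fraction = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  list(strategies = as.numeric(stats::runif(n_nodes) < init_coop_fraction),
       ma = numeric(n_nodes), mi = numeric(n_nodes),
       coop_history = matrix(numeric(0), nrow = 0, ncol = n_nodes))
}

#' One Monte Carlo sweep of the iterated game
#'
#' Performs `N` elementary steps so that every player gets, on average, one
#' chance to revise its strategy. An elementary step: draw a player `i` and a
#' layer `alpha`; `i` accrues its payoff against all `alpha`-neighbors; draw
#' a second layer `beta` (a different layer when `M > 1`) and a neighbor `j`
#' of `i` on `beta`, who accrues its payoff on `beta`; `i` then adopts `S_j`
#' with the Fermi probability built from the current `eta_i`, `psi_i`,
#' `theta_ij` and `delta_ij`. MA/MI increments from both accruals are kept.
#' After the sweep the per-node cooperation indicator is appended to
#' `coop_history`.
#'
#' @param state A [game_state()] list.
#' @param multiplex A `multiplex` object.
#' @param G A [communicability()] object, or `NULL` when `use_eta = FALSE`.
#' @param params A [game_params()] object.
#' @param theta,delta Similarity matrices (or `NULL` for 1).
#' @param use_eta,use_psi Disable an estimator (its factor becomes 1);
#'   used for degenerate well-mixed configurations.
#' @param audit Keep a log of adoptions (`i`, `from`, `to`)?
#' @param trace Keep a per-elementary-step interaction log (focal node,
#'   layer, payoff, counters, estimator values, partner, adoption flag)?
#' @return Updated state; if `audit`, an `adoptions` data.frame is attached;
#'   if `trace`, a `trace` data.frame is attached.
#' @export
monte_carlo_step <- function(state, multiplex, G, params,
                             theta = NULL, delta = NULL,
                             use_eta = TRUE, use_psi = TRUE,
                             audit = FALSE, trace = FALSE) {
  N <- multiplex$n_nodes
  M <- multiplex$n_layers
  strat <- state$strategies
  ma <- state$ma; mi <- state$mi
  log_i <- integer(0); log_from <- numeric(0); log_to <- numeric(0)
  tr <- if (trace) vector("list", N) else NULL

  for (step in seq_len(N)) {
    i <- sample.int(N, 1L)
    # layer for i's accrual; redraw if i is isolated there
    cand <- sample.int(M, M)
    alpha <- NA_integer_
    for (a in cand) if (length(multiplex$nbrs[[a]][[i]]) > 0L) { alpha <- a; break }
    if (is.na(alpha)) next                       # isolated everywhere
    acc_i <- accrue_payoff_and_bias(i, alpha, multiplex, strat, params)
    ma[i] <- ma[i] + acc_i$ma_inc; mi[i] <- mi[i] + acc_i$mi_inc

    # layer beta for the model neighbor: another layer when possible
    betas <- if (M == 1L) alpha else setdiff(sample.int(M, M), alpha)
    beta <- NA_integer_
    for (b in betas) if (length(multiplex$nbrs[[b]][[i]]) > 0L) { beta <- b; break }
    if (is.na(beta)) {
      if (M > 1L && length(multiplex$nbrs[[alpha]][[i]]) > 0L) beta <- alpha
      else next
    }
    nb <- multiplex$nbrs[[beta]][[i]]
    j <- nb[sample.int(length(nb), 1L)]
    acc_j <- accrue_payoff_and_bias(j, beta, multiplex, strat, params)
    ma[j] <- ma[j] + acc_j$ma_inc; mi[j] <- mi[j] + acc_j$mi_inc

    adopted <- FALSE
    eta_i <- psi_i <- NA_real_
    if (strat[i] != strat[j] || trace) {
      eta_i <- if (use_eta) eta(i, alpha, beta, strat, G, params) else 1
      psi_i <- if (use_psi) psi(ma[i], mi[i], params) else 1
    }
    if (strat[i] != strat[j]) {
      th <- if (is.null(theta)) 1 else theta[i, j]
      de <- if (is.null(delta)) 1 else delta[i, j]
      W <- fermi_adoption_prob(acc_i$payoff, acc_j$payoff, th, de, params,
                               eta_i, psi_i)
      if (stats::runif(1) < W) {
        if (audit) {
          log_i <- c(log_i, i); log_from <- c(log_from, strat[i])
          log_to <- c(log_to, strat[j])
        }
        strat[i] <- strat[j]
        adopted <- TRUE
      }
    }
    if (trace)
      tr[[step]] <- data.frame(
        node = i, layer = alpha, strategy = strat[i],
        payoff = acc_i$payoff, ma = ma[i], mi = mi[i],
        eta = eta_i, psi = psi_i,
        partner = j, partner_layer = beta, partner_payoff = acc_j$payoff,
        adopted = adopted)
  }

  state$strategies <- strat
  state$ma <- ma; state$mi <- mi
  state$coop_history <- rbind(state$coop_history, strat)
  if (audit)
    state$adoptions <- data.frame(i = log_i, from = log_from, to = log_to)
  if (trace)
    state$trace <- do.call(rbind, tr[!vapply(tr, is.null, logical(1))])
  state
}

#' Write a per-round game log as TSV
#'
#' Columns: round, node, strategy, payoff, ma, mi, eta, psi — one row per
#' elementary interaction of each sweep.
#'
#' @param traces List of `trace` data.frames, one per round (see
#'   [monte_carlo_step()] with `trace = TRUE`).
#' @param path Output file.
#' @export
write_game_log <- function(traces, path) {
  rows <- do.call(rbind, lapply(seq_along(traces), function(r)
    cbind(round = r, traces[[r]][, c("node", "strategy", "payoff",
                                     "ma", "mi", "eta", "psi")])))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cooperation density
#'
#' Fraction of cooperators in the population.
#'
#' @param strategies 0/1 strategy vector, or a [game_state()] list.
#' @return Scalar in `[0, 1]`.
#' @export
record_density <- function(strategies) {
  if (is.list(strategies)) strategies <- strategies$strategies
  mean(strategies)
}
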