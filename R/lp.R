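# Dense two-phase simplex for the small community-FBA linear programs.
#
# Solves   max/min  obj' v
#          s.t.     Aeq v  = beq
#                   Age v >= bge        (optional)
#                   lb <= v <= ub       (finite after capping)
#
# Variables are shifted to y = v - lb >= 0; upper bounds become explicit
# slack rows. Phase 1 minimizes artificial variables (infeasible if > 0);
# phase 2 uses Dantzig pricing with a Bland fallback for anti-cycling.
# Deterministic: no randomized tie-breaking anywhere.

simplex_lp <- function(obj, Aeq, beq, Age = NULL, bge = NULL,
                       lb, ub, maximize = TRUE, tol = 1e-9,
                       max_iter = 20000L) {
  n <- length(obj)
  ub <- pmin(ub, 1e5); lb <- pmax(lb, -1e5)
  if (any(lb > ub + tol))
    return(list(status = "infeasible", value = NA_real_, x = NULL))
  u <- ub - lb
  m_eq <- nrow(Aeq)
  m_ge <- if (is.null(Age)) 0L else nrow(Age)

  # rows: equalities | >= rows (with surplus) | upper bounds (with slack)
  b_eq <- beq - as.numeric(Aeq %*% lb)
  b_ge <- if (m_ge) bge - as.numeric(Age %*% lb) else numeric(0)

  n_sur <- m_ge; n_slk <- n
  ncols <- n + n_sur + n_slk
  m <- m_eq + m_ge + n
  A <- matrix(0, m, ncols)
  A[seq_len(m_eq), seq_len(n)] <- Aeq
  if (m_ge) {
    A[m_eq + seq_len(m_ge), seq_len(n)] <- Age
    A[cbind(m_eq + seq_len(m_ge), n + seq_len(m_ge))] <- -1
  }
  A[cbind(m_eq + m_ge + seq_len(n), seq_len(n))] <- 1
  A[cbind(m_eq + m_ge + seq_len(n), n + n_sur + seq_len(n))] <- 1
  bvec <- c(b_eq, b_ge, u)

  # normalize rhs signs
  neg <- bvec < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  bvec[neg] <- -bvec[neg]

  # basis: slack columns where they carry +1 after sign flip, else artificials
  basis <- integer(m)
  need_art <- rep(TRUE, m)
  slack_rows <- m_eq + m_ge + seq_len(n)
  ok <- !neg[slack_rows]
  basis[slack_rows[ok]] <- n + n_sur + which(ok)
  need_art[slack_rows[ok]] <- FALSE
  n_art <- sum(need_art)
  if (n_art) {
    Aart <- matrix(0, m, n_art)
    Aart[cbind(which(need_art), seq_len(n_art))] <- 1
    A <- cbind(A, Aart)
    basis[need_art] <- ncols + seq_len(n_art)
  }
  ntot <- ncol(A)

  Tb <- cbind(A, bvec)

  run_phase <- function(Tb, basis, cost, allowed, max_iter, tol) {
    m <- nrow(Tb); ntot <- ncol(Tb) - 1L
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > max_iter) return(list(status = "maxiter"))
      cb <- cost[basis]
      red <- cost - as.numeric(crossprod(Tb[, seq_len(ntot), drop = FALSE], cb))
      red[!allowed] <- 0
      red[basis] <- 0
      if (iter <= max_iter %/% 2L) {
        j <- which.min(red)                       # Dantzig
        if (red[j] >= -tol) break
      } else {
        cand <- which(red < -tol)                 # Bland fallback
        if (!length(cand)) break
        j <- cand[1]
      }
      col <- Tb[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratio <- Tb[pos, ntot + 1L] / col[pos]
      rmin <- min(ratio)
      sel <- pos[ratio <= rmin + tol]
      r <- sel[which.min(basis[sel])]             # Bland tie-break
      piv <- Tb[r, j]
      Tb[r, ] <- Tb[r, ] / piv
      other <- setdiff(seq_len(m), r)
      Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[r, ])
      basis[r] <- j
    }
    list(status = "optimal", Tb = Tb, basis = basis)
  }

  # phase 1
  if (n_art) {
    cost1 <- c(rep(0, ncols), rep(1, n_art))
    ph1 <- run_phase(Tb, basis, cost1, rep(TRUE, ntot), max_iter, tol)
    if (ph1$status != "optimal")
      return(list(status = ph1$status, value = NA_real_, x = NULL))
    Tb <- ph1$Tb; basis <- ph1$basis
    if (sum(Tb[, ntot + 1L][basis > ncols]) > 1e-7)
      return(list(status = "infeasible", value = NA_real_, x = NULL))
    # pivot lingering zero-valued artificials out where possible
    for (r in which(basis > ncols)) {
      j <- which(abs(Tb[r, seq_len(ncols)]) > tol)[1]
      if (!is.na(j)) {
        piv <- Tb[r, j]
        Tb[r, ] <- Tb[r, ] / piv
        other <- setdiff(seq_len(m), r)
        Tb[other, ] <- Tb[other, ] - outer(Tb[other, j], Tb[r, ])
        basis[r] <- j
      }
    }
  }

  # phase 2: artificial columns barred from entering
  cost2 <- c(obj * if (maximize) -1 else 1, rep(0, ntot - n))
  allowed <- c(rep(TRUE, ncols), rep(FALSE, ntot - ncols))
  ph2 <- run_phase(Tb, basis, cost2, allowed, max_iter, tol)
  if (ph2$status != "optimal")
    return(list(status = ph2$status, value = NA_real_, x = NULL))
  Tb <- ph2$Tb; basis <- ph2$basis

  y <- numeric(ntot)
  y[basis] <- Tb[, ntot + 1L]
  x <- y[seq_len(n)] + lb
  list(status = "optimal", value = sum(obj * x), x = x)
}
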