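# Dense linear and mixed-integer programming layer.
#
# The flux-balance and pathway-enumeration problems in this package are small
# (tens of variables), so a dense two-phase primal simplex with Bland's
# anti-cycling rule is sufficient and fully deterministic.  All variables must
# carry finite bounds, which every constraint-based problem here does (flux
# bounds are +/-1000 by convention).

#' Solve a bounded linear program
#'
#' Minimizes (or maximizes) `obj %*% x` subject to `A x = b`, `G x <= h` and
#' `lb <= x <= ub`.  All bounds must be finite; the feasible region is
#' therefore compact and the program can never be unbounded.
#'
#' @param obj numeric objective coefficients.
#' @param A,b optional equality constraint matrix and right-hand side.
#' @param G,h optional inequality (`<=`) constraint matrix and right-hand side.
#' @param lb,ub finite variable bounds.
#' @param maximize logical; maximize instead of minimize.
#' @param tol feasibility tolerance.
#' @return list with `status` ("optimal" or "infeasible"), solution `x` and
#'   `objval` (on the original objective scale).
#' @export
solve_lp <- function(obj, A = NULL, b = NULL, G = NULL, h = NULL,
                     lb, ub, maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (!all(is.finite(lb)) || !all(is.finite(ub)))
    stop("solve_lp() requires finite variable bounds")
  if (any(ub - lb < -tol)) return(list(status = "infeasible", x = NULL, objval = NA_real_))
  d <- pmax(ub - lb, 0)
  cc <- if (maximize) -obj else obj

  if (!is.null(A)) {
    A <- matrix(as.numeric(A), ncol = n)
    be <- as.numeric(b) - as.vector(A %*% lb)
  } else be <- numeric(0)
  if (!is.null(G)) {
    G <- matrix(as.numeric(G), ncol = n)
    hl <- as.numeric(h) - as.vector(G %*% lb)
  } else hl <- numeric(0)
  mE <- length(be); mL <- length(hl)
  m <- mE + mL + n                      # + one upper-bound row per variable
  nS <- mL + n                          # slack per inequality and bound row
  M <- matrix(0, m, n + nS)
  rhs <- numeric(m)
  if (mE) { M[seq_len(mE), seq_len(n)] <- A; rhs[seq_len(mE)] <- be }
  if (mL) {
    rows <- mE + seq_len(mL)
    M[rows, seq_len(n)] <- G
    M[cbind(rows, n + seq_len(mL))] <- 1
    rhs[rows] <- hl
  }
  brows <- mE + mL + seq_len(n)
  M[cbind(brows, seq_len(n))] <- 1
  M[cbind(brows, n + mL + seq_len(n))] <- 1
  rhs[brows] <- d

  neg <- rhs < 0
  if (any(neg)) { M[neg, ] <- -M[neg, , drop = FALSE]; rhs[neg] <- -rhs[neg] }

  # natural basis: slack columns that survived with coefficient +1
  basis <- integer(m)
  slack_col <- c(rep(NA_integer_, mE), n + seq_len(nS))
  for (i in seq_len(m)) {
    sc <- slack_col[i]
    if (!is.na(sc) && !neg[i]) basis[i] <- sc
  }
  art_rows <- which(basis == 0L)
  nA <- length(art_rows)
  if (nA) {
    Aart <- matrix(0, m, nA)
    Aart[cbind(art_rows, seq_len(nA))] <- 1
    M <- cbind(M, Aart)
    basis[art_rows] <- n + nS + seq_len(nA)
  }
  Tm <- cbind(M, rhs)
  ncols <- n + nS + nA

  if (nA) {
    costs1 <- c(rep(0, n + nS), rep(1, nA))
    r <- .simplex_core(Tm, basis, costs1, tol)
    Tm <- r$Tm; basis <- r$basis
    p1 <- sum(costs1[basis] * Tm[, ncols + 1L])
    if (p1 > 1e-7) return(list(status = "infeasible", x = NULL, objval = NA_real_))
    # drive artificials out of the basis, drop redundant rows
    drop_rows <- integer(0)
    for (i in seq_along(basis)) {
      if (basis[i] > n + nS) {
        piv <- which(abs(Tm[i, seq_len(n + nS)]) > tol)
        if (length(piv)) {
          j <- piv[1L]
          Tm[i, ] <- Tm[i, ] / Tm[i, j]
          for (k in seq_len(nrow(Tm))) if (k != i && abs(Tm[k, j]) > 0)
            Tm[k, ] <- Tm[k, ] - Tm[k, j] * Tm[i, ]
          basis[i] <- j
        } else drop_rows <- c(drop_rows, i)
      }
    }
    if (length(drop_rows)) { Tm <- Tm[-drop_rows, , drop = FALSE]; basis <- basis[-drop_rows] }
    Tm <- Tm[, c(seq_len(n + nS), ncols + 1L), drop = FALSE]
  }

  costs2 <- c(cc, rep(0, nS))
  r <- .simplex_core(Tm, basis, costs2, tol)
  if (r$status != "optimal") stop("simplex failed to converge (", r$status, ")")
  z <- numeric(n + nS)
  z[r$basis] <- r$Tm[, ncol(r$Tm)]
  x <- lb + z[seq_len(n)]
  list(status = "optimal", x = x, objval = sum(obj * x))
}

# One pass of the primal simplex with Bland's rule on a normalized tableau.
# Tm: m x (N+1), last column is the RHS; basis columns form an identity.
.simplex_core <- function(Tm, basis, costs, tol = 1e-9, maxit = 50000L) {
  N <- ncol(Tm) - 1L
  for (it in seq_len(maxit)) {
    cb <- costs[basis]
    red <- costs[seq_len(N)] - drop(cb %*% Tm[, seq_len(N), drop = FALSE])
    ent <- which(red < -tol)
    if (!length(ent)) return(list(Tm = Tm, basis = basis, status = "optimal"))
    j <- ent[1L]                                  # Bland: smallest index
    col <- Tm[, j]
    pos <- which(col > tol)
    if (!length(pos)) return(list(Tm = Tm, basis = basis, status = "unbounded"))
    ratio <- Tm[pos, N + 1L] / col[pos]
    best <- pos[ratio <= min(ratio) + tol]
    i <- best[which.min(basis[best])]             # Bland tie-break
    Tm[i, ] <- Tm[i, ] / Tm[i, j]
    piv <- Tm[i, ]
    upd <- which(abs(Tm[, j]) > 0)
    upd <- upd[upd != i]
    if (length(upd)) Tm[upd, ] <- Tm[upd, , drop = FALSE] - outer(Tm[upd, j], piv)
    basis[i] <- j
  }
  list(Tm = Tm, basis = basis, status = "maxit")
}

#' Solve a mixed-binary linear program by branch and bound
#'
#' Same constraint interface as [solve_lp()]; the variables indexed by
#' `bin_idx` are additionally restricted to {0, 1}.  Depth-first search,
#' branching on the most fractional binary (lowest index on ties), exploring
#' the zero branch first, which makes the search fully deterministic.
#'
#' @inheritParams solve_lp
#' @param bin_idx integer indices of binary variables.
#' @param int_tol integrality tolerance.
#' @return list with `status` ("optimal" or "infeasible"), `x`, `objval`.
#' @export
solve_milp <- function(obj, A = NULL, b = NULL, G = NULL, h = NULL,
                       lb, ub, bin_idx = integer(0), maximize = FALSE,
                       int_tol = 1e-6) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n); ub <- rep_len(as.numeric(ub), n)
  sense <- if (maximize) -1 else 1
  best <- NULL; best_val <- Inf
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(obj, A, b, G, h, node$lb, node$ub, maximize = maximize)
    if (rel$status != "optimal") next
    val <- sense * rel$objval
    if (val >= best_val - 1e-9) next
    frac <- abs(rel$x[bin_idx] - round(rel$x[bin_idx]))
    if (!length(bin_idx) || max(frac) <= int_tol) {
      x <- rel$x
      x[bin_idx] <- round(x[bin_idx])
      best <- x; best_val <- val
      next
    }
    j <- bin_idx[which.max(frac)]
    up <- node; up$lb[j] <- 1
    dn <- node; dn$ub[j] <- 0
    stack[[length(stack) + 1L]] <- up   # popped last
    stack[[length(stack) + 1L]] <- dn   # zero branch explored first
  }
  if (is.null(best)) return(list(status = "infeasible", x = NULL, objval = NA_real_))
  list(status = "optimal", x = best, objval = sense * best_val)
}
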