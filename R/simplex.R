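# Dense two-phase primal simplex.
#
# Solves  min c'x  s.t.  A x (<=|>=|=) b,  x >= 0.
# Phase 1 minimizes the sum of artificial variables to find a basic feasible
# solution; phase 2 optimizes the original objective. Pivoting uses Dantzig's
# most-negative-reduced-cost rule with an automatic switch to Bland's rule
# after a stretch of degenerate pivots, which guarantees termination.
# Written for moderate dense problems (a few hundred rows/columns); returns
# the optimal vertex, its basis, reduced costs (for degeneracy flags) and a
# status of "optimal", "infeasible" or "unbounded".

simplex_solve <- function(c_obj, A, dir, b, max_iter = 20000L) {
  stopifnot(length(dir) == nrow(A), length(b) == nrow(A),
            length(c_obj) == ncol(A))
  m <- nrow(A)
  n <- ncol(A)

  # normalize to b >= 0
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  dir[flip] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[flip]]

  n_slack <- sum(dir != "=")
  need_art <- dir %in% c(">=", "=")
  n_art <- sum(need_art)
  ncol_t <- n + n_slack + n_art

  Tab <- matrix(0, m, ncol_t)
  Tab[, seq_len(n)] <- A
  slack_col <- integer(m)
  k <- n
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      k <- k + 1L; Tab[i, k] <- 1; slack_col[i] <- k
    } else if (dir[i] == ">=") {
      k <- k + 1L; Tab[i, k] <- -1; slack_col[i] <- k
    }
  }
  art_col <- integer(m)
  for (i in which(need_art)) {
    k <- k + 1L; Tab[i, k] <- 1; art_col[i] <- k
  }
  basis <- ifelse(need_art, art_col, slack_col)
  rhs <- b

  pivot <- function(Tab, rhs, pr, pc) {
    pv <- Tab[pr, pc]
    Tab[pr, ] <- Tab[pr, ] / pv
    rhs[pr] <- rhs[pr] / pv
    others <- setdiff(seq_len(nrow(Tab)), pr)
    f <- Tab[others, pc]
    Tab[others, ] <- Tab[others, , drop = FALSE] - outer(f, Tab[pr, ])
    rhs[others] <- rhs[others] - f * rhs[pr]
    list(Tab = Tab, rhs = rhs)
  }

  run_phase <- function(Tab, rhs, basis, cost, allowed) {
    it <- 0L
    stall <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "iteration-limit", Tab = Tab,
                                     rhs = rhs, basis = basis))
      cb <- cost[basis]
      red <- cost - as.numeric(crossprod(cb, Tab))  # reduced costs
      red[basis] <- 0
      cand <- which(allowed & red < -1e-9)
      if (!length(cand)) {
        return(list(status = "optimal", Tab = Tab, rhs = rhs, basis = basis,
                    reduced = red))
      }
      pc <- if (stall > 2L * length(basis)) min(cand) else
        cand[which.min(red[cand])]  # Bland after stalling, else Dantzig
      col <- Tab[, pc]
      pos <- which(col > 1e-9)
      if (!length(pos)) return(list(status = "unbounded", Tab = Tab,
                                    rhs = rhs, basis = basis))
      ratio <- rhs[pos] / col[pos]
      pr <- pos[ratio <= min(ratio) + 1e-12]
      pr <- pr[which.min(basis[pr])]  # Bland-style tie-break on leaving var
      stall <- if (min(ratio) < 1e-11) stall + 1L else 0L
      out <- pivot(Tab, rhs, pr, pc)
      Tab <- out$Tab
      rhs <- out$rhs
      basis[pr] <- pc
    }
  }

  allowed <- rep(TRUE, ncol_t)
  if (n_art > 0) {
    cost1 <- numeric(ncol_t)
    cost1[art_col[art_col > 0]] <- 1
    ph1 <- run_phase(Tab, rhs, basis, cost1, allowed)
    if (ph1$status != "optimal") {
      return(list(status = "infeasible", x = NULL))
    }
    obj1 <- sum(cost1[ph1$basis] * ph1$rhs)
    if (obj1 > 1e-7) return(list(status = "infeasible", x = NULL))
    Tab <- ph1$Tab
    rhs <- ph1$rhs
    basis <- ph1$basis
    # drive lingering (degenerate) artificials out of the basis
    arts <- art_col[art_col > 0]
    for (pr in which(basis %in% arts)) {
      repl <- which(abs(Tab[pr, seq_len(n + n_slack)]) > 1e-9)
      if (length(repl)) {
        out <- pivot(Tab, rhs, pr, repl[1])
        Tab <- out$Tab
        rhs <- out$rhs
        basis[pr] <- repl[1]
      }
    }
    allowed[arts] <- FALSE
  }

  cost2 <- c(c_obj, numeric(ncol_t - n))
  ph2 <- run_phase(Tab, rhs, basis, cost2, allowed)
  if (ph2$status == "unbounded") return(list(status = "unbounded", x = NULL))
  if (ph2$status != "optimal") return(list(status = "error", x = NULL))
  x <- numeric(ncol_t)
  x[ph2$basis] <- ph2$rhs
  # degenerate optimum: a nonbasic structural/slack column with (numerically)
  # zero reduced cost signals alternative optima
  nonbasic <- setdiff(which(allowed), ph2$basis)
  alt <- any(abs(ph2$reduced[nonbasic]) < 1e-9)
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(c_obj * x[seq_len(n)]), degenerate = alt)
}
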