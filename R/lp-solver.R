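# Internal linear-programming layer.
#
# All flux problems in the package are dense and toy-scale. The LP engine is
# a dense two-phase primal simplex with Bland's anti-cycling rule: slower in
# iterations than steepest-edge codes but deterministic and guaranteed to
# terminate, which the degenerate steady-state polytopes here (many zero
# right-hand sides, redundant rows) demand. Mixed-integer problems (iMAT,
# MADE) are solved by a depth-first branch-and-bound over the same LP
# relaxation.

LP_TOL <- 1e-9

# Core simplex on the standard form  min c'x  s.t.  A x {<=,>=,=} b, x >= 0.
# Rows must already have b >= 0. Returns list(status, x, objval).
simplex_core <- function(cvec, A, dir, b) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(b >= -1e-12))
  b <- pmax(b, 0)
  # slack (+1) for <=, surplus (-1) for >=; artificials for >= and =
  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ntot <- n + n_slack + n_surp + n_art
  Tb <- matrix(0, m, ntot + 1L)
  Tb[, seq_len(n)] <- A
  Tb[, ntot + 1L] <- b
  basis <- integer(m)
  js <- n; ja <- n + n_slack + n_surp
  for (i in seq_len(m)) {
    if (dir[i] == "<=") {
      js <- js + 1L; Tb[i, js] <- 1; basis[i] <- js
    } else {
      if (dir[i] == ">=") { js_s <- n + n_slack + sum(dir[seq_len(i)] == ">="); Tb[i, js_s] <- -1 }
      ja <- ja + 1L; Tb[i, ja] <- 1; basis[i] <- ja
    }
  }
  art_cols <- seq.int(n + n_slack + n_surp + 1L, ntot)
  if (n_art == 0L) art_cols <- integer()

  run_phase <- function(Tb, basis, cost, banned) {
    repeat {
      # reduced costs: c_j - c_B' * col_j (tableau kept in canonical form)
      cb <- cost[basis]
      rc <- cost[seq_len(ntot)] - as.numeric(crossprod(cb, Tb[, seq_len(ntot), drop = FALSE]))
      rc[banned] <- Inf
      rc[basis] <- Inf     # basic columns have rc 0; exclude for Bland
      enter <- which(rc < -1e-9)
      if (!length(enter)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- enter[1L]                         # Bland: smallest index
      col <- Tb[, j]
      pos <- which(col > 1e-9)
      if (!length(pos)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[pos, ntot + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + 1e-12]
      i <- cand[which.min(basis[cand])]      # Bland: smallest basic index leaves
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      colj <- Tb[, j]; colj[i] <- 0
      Tb <- Tb - outer(colj, Tb[i, ])
      basis[i] <- j
    }
  }

  # phase 1
  if (n_art > 0L) {
    c1 <- numeric(ntot); c1[art_cols] <- 1
    ph1 <- run_phase(Tb, basis, c1, banned = integer())
    if (ph1$status != "optimal") return(list(status = "infeasible"))
    Tb <- ph1$Tb; basis <- ph1$basis
    if (sum(Tb[match(intersect(basis, art_cols), basis), ntot + 1L]) > 1e-7 ||
        sum(c1[basis] * Tb[, ntot + 1L]) > 1e-7)
      return(list(status = "infeasible"))
    # drive degenerate artificials out of the basis
    for (i in which(basis %in% art_cols)) {
      row <- Tb[i, seq_len(n + n_slack + n_surp)]
      j <- which(abs(row) > 1e-9)[1L]
      if (is.na(j)) { Tb[i, ] <- 0; next }   # redundant row
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      colj <- Tb[, j]; colj[i] <- 0
      Tb <- Tb - outer(colj, Tb[i, ])
      basis[i] <- j
    }
  }
  # phase 2 (artificial columns barred)
  c2 <- numeric(ntot); c2[seq_len(n)] <- cvec
  ph2 <- run_phase(Tb, basis, c2, banned = art_cols)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  Tb <- ph2$Tb; basis <- ph2$basis
  x <- numeric(ntot)
  x[basis] <- Tb[, ntot + 1L]
  list(status = "optimal", x = x[seq_len(n)], objval = sum(cvec * x[seq_len(n)]))
}

#' @noRd
#' @param obj objective coefficients (length n)
#' @param mat constraint matrix (m x n), possibly with 0 rows
#' @param dir character vector in c("<=", ">=", "=")
#' @param rhs right-hand sides
#' @param lower,upper finite variable bounds
#' @return list(status = "optimal"|"infeasible"|"unbounded", objval, solution)
solve_lp <- function(obj, mat, dir, rhs, lower, upper, maximize = FALSE) {
  n <- length(obj)
  stopifnot(all(is.finite(lower)), all(is.finite(upper)))
  if (any(lower > upper + 1e-12))
    return(list(status = "infeasible", objval = NA_real_, solution = rep(NA_real_, n)))
  mat <- as.matrix(mat)
  if (length(dir) != nrow(mat) || length(rhs) != nrow(mat))
    stop("constraint dimensions disagree")

  # substitute x = v - lower, x >= 0; upper bounds become rows
  shift <- lower
  rhs2 <- rhs - as.numeric(mat %*% shift)
  A <- rbind(mat, diag(n))
  d <- c(dir, rep("<=", n))
  b <- c(rhs2, upper - lower)

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    d[neg] <- ifelse(d[neg] == "<=", ">=", ifelse(d[neg] == ">=", "<=", "="))
  }
  cvec <- if (maximize) -obj else obj
  res <- simplex_core(cvec, A, d, b)
  if (res$status != "optimal")
    return(list(status = res$status, objval = NA_real_, solution = rep(NA_real_, n)))
  sol <- res$x + shift
  list(status = "optimal", objval = sum(obj * sol), solution = sol)
}

#' Depth-first branch-and-bound for binary MILPs.
#'
#' Branch order and incumbent updates are deterministic, so repeated runs on
#' the same instance return bit-identical solutions.
#' @noRd
solve_milp <- function(obj, mat, dir, rhs, lower, upper, binary_idx,
                       maximize = FALSE, int_tol = 1e-6, gap_tol = 1e-7) {
  best <- new.env(parent = emptyenv())
  best$objval <- if (maximize) -Inf else Inf
  best$solution <- NULL
  sense <- if (maximize) 1 else -1

  recurse <- function(lo, up) {
    rel <- solve_lp(obj, mat, dir, rhs, lo, up, maximize = maximize)
    if (rel$status != "optimal") return(invisible())
    if (!is.null(best$solution) &&
        sense * rel$objval <= sense * best$objval + gap_tol) return(invisible())
    frac <- abs(rel$solution[binary_idx] - round(rel$solution[binary_idx]))
    viol <- which(frac > int_tol)
    if (length(viol) == 0L) {
      best$objval <- rel$objval
      best$solution <- rel$solution
      return(invisible())
    }
    j <- binary_idx[viol[1L]]
    up0 <- up; up0[j] <- 0; recurse(lo, up0)          # x_j = 0 branch first
    lo1 <- lo; lo1[j] <- 1; recurse(lo1, up)
    invisible()
  }
  recurse(lower, upper)
  if (is.null(best$solution))
    return(list(status = "infeasible", objval = NA_real_, solution = NULL))
  sol <- best$solution
  sol[binary_idx] <- round(sol[binary_idx])
  list(status = "optimal", objval = best$objval, solution = sol)
}
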