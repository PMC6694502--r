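# Independent oracles, written against the definitions rather than the
# package's code paths.

# Two-sided Fisher exact p for a 2x2 table by hypergeometric tail summation:
# sum the probabilities of all tables with the same margins that are at most
# as probable as the observed one (with the customary relative slack for
# floating-point equality).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n_ <- c + d         # row 2 margin
  k <- a + c          # column 1 margin
  support <- max(0L, k - n_):min(k, m)
  probs <- stats::dhyper(support, m, n_, k)
  p_obs <- stats::dhyper(a, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of all C(n+m, n)
# assignments of the pooled values; U computed by pair counting (greater /
# half for ties), not by rank sums.
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  N <- length(pooled); nx <- length(x)
  u_of <- function(xi) {
    xs <- pooled[xi]; ys <- pooled[-xi]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  splits <- utils::combn(N, nx)
  us <- apply(splits, 2L, u_of)
  u_obs <- u_of(seq_len(nx))
  lo <- mean(us <= u_obs + 1e-12)
  hi <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(lo, hi))
}

# iMAT optimum by exhaustive enumeration: over every subset of high
# reactions forced on (flux >= eps forward; generated toys are
# irreversible) and every subset of low reactions forced off, check LP
# feasibility and take the best total reward.
oracle_imat_enum <- function(model, status, eps) {
  high <- model$reactions$id[status[model$reactions$id] == "high"]
  low <- model$reactions$id[status[model$reactions$id] == "low"]
  stopifnot(all(model$reactions$lower_bound[match(high, model$reactions$id)] >= 0))
  n <- nrow(model$reactions)
  feasible <- function(on, off) {
    lo <- model$reactions$lower_bound; up <- model$reactions$upper_bound
    i_on <- match(on, model$reactions$id); i_off <- match(off, model$reactions$id)
    lo[i_on] <- pmax(lo[i_on], eps)
    lo[i_off] <- 0; up[i_off] <- 0
    r <- sgpr:::solve_lp(numeric(n), as.matrix(model$stoich),
                         rep("=", nrow(model$stoich)), numeric(nrow(model$stoich)),
                         lo, up)
    r$status == "optimal"
  }
  subsets <- function(v) {
    if (!length(v)) return(list(character()))
    out <- list()
    for (mask in 0:(2^length(v) - 1L))
      out[[mask + 1L]] <- v[bitwAnd(mask, 2^(seq_along(v) - 1L)) > 0]
    out
  }
  best <- 0L
  for (on in subsets(high)) for (off in subsets(low)) {
    reward <- length(on) + length(off)
    if (reward > best && feasible(on, off)) best <- reward
  }
  best
}

# FBA optimum through a second, independently written LP formulation:
# explicit forward/backward split v = f - b with box bounds only, solved by
# the raw standard-form simplex (no variable shifting).
oracle_fba_split <- function(model, objective = model$objective) {
  n <- nrow(model$reactions)
  S <- as.matrix(model$stoich)
  lb <- model$reactions$lower_bound; ub <- model$reactions$upper_bound
  stopifnot(all(lb <= 0), all(ub >= 0))  # oracle limited to zero-spanning bounds
  A <- rbind(cbind(S, -S), cbind(diag(n), matrix(0, n, n)),
             cbind(matrix(0, n, n), diag(n)))
  dir <- c(rep("=", nrow(S)), rep("<=", 2 * n))
  rhs <- c(numeric(nrow(S)), pmax(ub, 0), pmax(-lb, 0))
  obj <- numeric(2 * n)
  oi <- match(objective, model$reactions$id)
  obj[oi] <- -1; obj[n + oi] <- 1       # minimize -(f - b)
  res <- sgpr:::simplex_core(obj, A, dir, rhs)
  stopifnot(res$status == "optimal")
  -res$objval
}
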