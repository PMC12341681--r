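# Linear programming backend.
#
# FBA and FVA reduce to LPs of the form
#     max/min  a' v   s.t.  S v = 0,  L <= v <= U,  (optionally) c' v >= rhs
# solved by a two-phase dense simplex with Bland's anti-cycling rule.
# Variables are shifted by their lower bounds, upper bounds become slack
# rows, and the optional inequality gains a surplus variable, giving a
# standard-form problem min a'x, A x = b, x >= 0 with b >= 0. All
# variables are box-bounded, so the LP is never unbounded. Problem sizes
# here are tiny (tens of columns), so clarity beats sparsity.

# min cost'x  s.t.  A x = b (b >= 0), x >= 0. Two-phase; Bland's rule.
simplex_standard_form <- function(A, b, cost, tol = 1e-9,
                                  max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(all(b >= 0))
  Tab <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)              # start from the artificial basis
  art <- n + seq_len(m)

  pivot <- function(Tab, i, j) {
    Tab[i, ] <- Tab[i, ] / Tab[i, j]
    rest <- setdiff(seq_len(nrow(Tab)), i)
    Tab[rest, ] <- Tab[rest, ] - outer(Tab[rest, j], Tab[i, ])
    Tab
  }
  run <- function(Tab, basis, cost_full, allowed) {
    rhs_col <- ncol(Tab)
    for (it in seq_len(max_iter)) {
      cb <- cost_full[basis]
      red <- cost_full[allowed] -
        as.numeric(cb %*% Tab[, allowed, drop = FALSE])
      ent <- allowed[red < -tol]
      if (!length(ent)) {
        return(list(Tab = Tab, basis = basis, status = "optimal"))
      }
      j <- min(ent)                     # Bland: smallest entering index
      col <- Tab[, j]
      pos <- which(col > tol)
      if (!length(pos)) return(list(status = "unbounded"))
      ratios <- Tab[pos, rhs_col] / col[pos]
      rmin <- min(ratios)
      cand <- pos[ratios <= rmin + tol]
      i <- cand[which.min(basis[cand])] # Bland: smallest leaving index
      Tab <- pivot(Tab, i, j)
      basis[i] <- j
    }
    list(status = "maxiter")
  }

  # phase 1: minimize the sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  p1 <- run(Tab, basis, cost1, allowed = seq_len(n + m))
  if (p1$status != "optimal") {
    stop("LP phase 1 did not converge (", p1$status, ")")
  }
  Tab <- p1$Tab; basis <- p1$basis
  if (sum(Tab[, ncol(Tab)][basis %in% art]) > 1e-7) {
    return(list(status = "infeasible"))
  }
  # drive any zero-level artificials out of the basis
  for (i in which(basis %in% art)) {
    j <- which(abs(Tab[i, seq_len(n)]) > tol)[1]
    if (!is.na(j)) {
      Tab <- pivot(Tab, i, j)
      basis[i] <- j
    }                                   # else: redundant row, harmless
  }
  # phase 2 over original columns only
  cost2 <- c(cost, rep(0, m))
  p2 <- run(Tab, basis, cost2, allowed = seq_len(n))
  if (p2$status != "optimal") {
    stop("LP phase 2 did not converge (", p2$status, ")")
  }
  x <- numeric(n)
  keep <- p2$basis <= n
  x[p2$basis[keep]] <- p2$Tab[keep, ncol(p2$Tab)]
  list(status = "optimal", x = x, value = sum(cost * x))
}

solve_bounded_lp <- function(a, S, L, U, sense = c("max", "min"),
                             extra = NULL, tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(a)
  stopifnot(length(L) == n, length(U) == n, ncol(S) == n)
  m <- nrow(S)
  has_extra <- !is.null(extra)
  # columns: x (n), upper-bound slacks (n), surplus for the extra row (0/1)
  ncols <- 2L * n + as.integer(has_extra)
  A <- matrix(0, m + n + as.integer(has_extra), ncols)
  b <- numeric(nrow(A))
  A[seq_len(m), seq_len(n)] <- S
  b[seq_len(m)] <- as.numeric(-S %*% L)
  A[m + seq_len(n), seq_len(n)] <- diag(n)
  A[m + seq_len(n), n + seq_len(n)] <- diag(n)
  b[m + seq_len(n)] <- U - L
  if (has_extra) {                      # coef'v >= rhs  ->  coef'x - t = rhs'
    r <- nrow(A)
    A[r, seq_len(n)] <- extra$coef
    A[r, ncols] <- -1
    b[r] <- extra$rhs - sum(extra$coef * L)
  }
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  cost <- numeric(ncols)
  cost[seq_len(n)] <- if (sense == "max") -a else a
  res <- simplex_standard_form(A, b, cost, tol = tol)
  if (res$status == "infeasible") {
    return(list(status = "infeasible", v = NULL, value = NA_real_))
  }
  v <- res$x[seq_len(n)] + L
  list(status = "optimal", v = v, value = sum(a * v))
}

#' Flux balance analysis
#'
#' Solves the linear program max c'v subject to S v = 0 and L <= v <= U,
#' returning an optimal steady-state flux distribution. Infeasibility is
#' reported in the `status` field, never masked with zero fluxes.
#'
#' @param model a `constraint_model`.
#' @param objective NULL (use the model's declared objective), a reaction
#'   id, or a named weight vector; see [objective_vector()].
#' @param sense `"max"` (default) or `"min"`.
#' @return An `fba_result`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective_value` (c'v; `NA` if infeasible) and
#'   `fluxes` (named vector over all reactions, `NULL` if infeasible).
#' @seealso [run_fva()]
#' @export
run_fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  validate_constraint_model(model)
  w <- objective_vector(model, objective)
  sol <- solve_bounded_lp(unname(w), model$S,
                          model$reactions$lower, model$reactions$upper,
                          sense = sense)
  fluxes <- if (is.null(sol$v)) NULL else
    stats::setNames(sol$v, model$reactions$id)
  structure(list(status = sol$status, objective_value = sol$value,
                 fluxes = fluxes, objective = w, sense = sense),
            class = "fba_result")
}

#' @export
print.fba_result <- function(x, ...) {
  cat("FBA:", x$status)
  if (x$status == "optimal") cat(", objective =", format(x$objective_value))
  cat("\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each reaction r, computes the minimum and maximum flux minF(r) and
#' maxF(r) compatible with retaining at least a fraction `q` of the FBA
#' optimum: max/min v(r) subject to S v = 0, L <= v <= U and c'v >= q * mu.
#' The flux variability of r is FV(r) = maxF(r) - minF(r).
#'
#' @param model a `constraint_model`.
#' @param objective as in [run_fba()].
#' @param q fraction of the optimum retained, in [0, 1]; default 0.999
#'   (q = 1 pins the objective to its optimum exactly and can make the
#'   reduced space numerically fragile, hence the slightly relaxed default).
#' @param reactions reaction ids to analyse (default: all).
#' @param epsilon dormancy threshold passed through to the `dormant`
#'   column, in mmol gDW^-1 h^-1; see [is_dormant()].
#' @return An `fva_result`: data.frame with columns `reaction_id`, `minF`,
#'   `maxF`, `FV`, `dormant`; attributes `q`, `mu` (the FBA optimum) and
#'   `epsilon`.
#' @export
run_fva <- function(model, objective = NULL, q = 0.999, reactions = NULL,
                    epsilon = 1e-2) {
  stopifnot(q >= 0, q <= 1)
  validate_constraint_model(model)
  w <- objective_vector(model, objective)
  base <- run_fba(model, objective)
  if (base$status != "optimal") {
    stop("FVA requires a feasible base model; FBA status was ", base$status)
  }
  mu <- base$objective_value
  ids <- model$reactions$id
  if (is.null(reactions)) reactions <- ids
  unknown <- setdiff(reactions, ids)
  if (length(unknown)) stop("unknown reaction(s): ", toString(unknown))
  extra <- list(coef = unname(w), rhs = q * mu)
  L <- model$reactions$lower; U <- model$reactions$upper
  out <- lapply(reactions, function(r) {
    a <- as.numeric(ids == r)
    lo <- solve_bounded_lp(a, model$S, L, U, "min", extra = extra)
    hi <- solve_bounded_lp(a, model$S, L, U, "max", extra = extra)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem infeasible for reaction ", r)
    }
    c(lo$value, hi$value)
  })
  minF <- vapply(out, `[`, numeric(1), 1)
  maxF <- vapply(out, `[`, numeric(1), 2)
  # solver jitter can leave minF a hair above maxF on pinned reactions
  sw <- minF > maxF
  if (any(sw)) {
    mid <- (minF[sw] + maxF[sw]) / 2
    minF[sw] <- pmin(minF[sw], mid); maxF[sw] <- pmax(maxF[sw], mid)
  }
  res <- data.frame(reaction_id = reactions, minF = minF, maxF = maxF,
                    FV = maxF - minF,
                    dormant = is_dormant(minF, maxF, epsilon),
                    stringsAsFactors = FALSE)
  structure(res, q = q, mu = mu, epsilon = epsilon,
            class = c("fva_result", "data.frame"))
}

#' Is a reaction dormant?
#'
#' A reaction is dormant when its steady-state flux is necessarily
#' (numerically) zero: |minF(r)| <= epsilon and |maxF(r)| <= epsilon. The
#' threshold absorbs LP solver noise; both comparisons are inclusive.
#'
#' @param minF,maxF FVA minimum and maximum fluxes (vectorised).
#' @param epsilon threshold in mmol gDW^-1 h^-1; default 1e-2.
#' @return logical vector.
#' @export
is_dormant <- function(minF, maxF, epsilon = 1e-2) {
  stopifnot(all(minF <= maxF + 1e-12))
  abs(minF) <= epsilon & abs(maxF) <= epsilon
}

#' Count dormant reactions in an FVA result
#'
#' @param fva an `fva_result` (or any data.frame with `minF`, `maxF`).
#' @param epsilon dormancy threshold; default 1e-2.
#' @return integer count.
#' @export
count_dormant <- function(fva, epsilon = 1e-2) {
  if (nrow(fva) == 0) return(0L)
  sum(is_dormant(fva$minF, fva$maxF, epsilon))
}
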