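# Brute-force LP oracle: enumerate all basic solutions (vertices) of
# {A v = b, L <= v <= U} by fixing every choice of n - rank(A) variables at
# a bound and solving for the rest. Exponential, so only for fixtures with
# a handful of reactions; independent of the package's simplex code.

oracle_vertices <- function(A, b, L, U, tol = 1e-8) {
  n <- ncol(A)
  k <- qr(A)$rank
  nf <- n - k
  verts <- list()
  consider <- function(v) {
    if (max(abs(A %*% v - b)) < tol &&
        all(v >= L - tol) && all(v <= U + tol)) {
      verts[[length(verts) + 1]] <<- pmin(pmax(v, L), U)
    }
  }
  if (nf == 0) {
    v <- tryCatch(qr.solve(A, b), error = function(e) NULL)
    if (!is.null(v)) consider(as.numeric(v))
  } else {
    for (F in utils::combn(n, nf, simplify = FALSE)) {
      B <- setdiff(seq_len(n), F)
      AB <- A[, B, drop = FALSE]
      if (qr(AB)$rank < length(B)) next
      for (mask in 0:(2^nf - 1)) {
        at_upper <- as.logical(bitwAnd(mask, 2^(seq_len(nf) - 1)))
        vF <- ifelse(at_upper, U[F], L[F])
        rhs <- b - A[, F, drop = FALSE] %*% vF
        vB <- tryCatch(as.numeric(qr.solve(AB, rhs)),
                       error = function(e) NULL)
        if (is.null(vB)) next
        v <- numeric(n); v[F] <- vF; v[B] <- vB
        consider(v)
      }
    }
  }
  if (!length(verts)) return(NULL)
  do.call(rbind, verts)
}

# Optimum of max/min obj'v over the polytope, by vertex enumeration.
oracle_lp_optimum <- function(S, L, U, obj, sense = "max",
                              extra = NULL) {
  A <- S; b <- rep(0, nrow(S))
  if (!is.null(extra)) {  # extra: coef'v >= rhs, via a bounded surplus var
    smax <- sum(abs(extra$coef) * pmax(abs(L), abs(U))) + abs(extra$rhs) + 1
    A <- rbind(cbind(A, 0), c(extra$coef, -1))
    b <- c(b, extra$rhs)
    L <- c(L, 0); U <- c(U, smax)
    obj <- c(obj, 0)
  }
  V <- oracle_vertices(A, b, L, U)
  if (is.null(V)) return(NA_real_)
  vals <- V %*% obj
  if (sense == "max") max(vals) else min(vals)
}

oracle_fba <- function(model, objective = NULL, sense = "max") {
  w <- objective_vector(model, objective)
  oracle_lp_optimum(model$S, model$reactions$lower, model$reactions$upper,
                    unname(w), sense)
}

oracle_fva <- function(model, objective = NULL, q = 0.999) {
  w <- unname(objective_vector(model, objective))
  mu <- oracle_fba(model, objective)
  extra <- list(coef = w, rhs = q * mu)
  ids <- model$reactions$id
  t(vapply(seq_along(ids), function(i) {
    a <- as.numeric(seq_along(ids) == i)
    c(minF = oracle_lp_optimum(model$S, model$reactions$lower,
                               model$reactions$upper, a, "min", extra),
      maxF = oracle_lp_optimum(model$S, model$reactions$lower,
                               model$reactions$upper, a, "max", extra))
  }, c(minF = 0, maxF = 0)))
}

# Minimal three-variable branch model: inflow -> A (<= cap), A -> biomass,
# A -> product. The growth/product bifurcation in miniature.
mini_branch_model <- function(cap = 10) {
  constraint_model(
    reactions = data.frame(id = c("IN", "BIO", "PROD"),
                           name = c("IN", "BIO", "PROD"),
                           lower = 0, upper = c(cap, 1000, 1000),
                           objective_coefficient = c(0, 1, 0),
                           stringsAsFactors = FALSE),
    metabolites = data.frame(id = "A", name = "A", compartment = "c",
                             stringsAsFactors = FALSE),
    S = matrix(c(1, -1, -1), 1, 3))
}
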