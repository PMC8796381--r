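# Independent LP oracle used to cross-check the package's simplex backend.
#
# Deliberately a different codebase, algorithm variant and formulation from
# the implementation under test: a pure-R two-phase full-tableau simplex
# with Bland's rule throughout (termination guaranteed, no Dantzig pricing),
# run on the explicit standard form -- variables shifted to x = v - lb >= 0,
# fixed variables eliminated, upper bounds and the optional
# objective-fraction row turned into equality rows with hand-added slack
# variables, right-hand sides sign-normalized, redundant rows dropped at the
# phase-1/phase-2 transition. The equality matrix is rebuilt entry-by-entry
# from the per-reaction stoichiometry dictionaries rather than via
# stoichiometry_matrix(). Requires finite bounds, which all fixture models
# have.

# min/max cost'z subject to M z = rhs (rhs >= 0), z >= 0
oracle_simplex_std <- function(M, rhs, cost, maximize = FALSE, tol = 1e-9) {
  m <- nrow(M)
  n <- ncol(M)
  stopifnot(all(rhs >= 0), length(cost) == n)
  if (maximize) cost <- -cost

  Tb <- cbind(M, diag(m), rhs, deparse.level = 0)
  basis <- n + seq_len(m)
  rhs_col <- function() ncol(Tb)

  pivot_on <- function(i, j) {
    Tb[i, ] <<- Tb[i, ] / Tb[i, j]
    for (r in seq_len(nrow(Tb))) {
      if (r != i && Tb[r, j] != 0) Tb[r, ] <<- Tb[r, ] - Tb[r, j] * Tb[i, ]
    }
    basis[i] <<- j
  }

  # Bland's rule iteration over the allowed columns; returns "optimal" or
  # "unbounded"
  run_phase <- function(cvec, allowed) {
    repeat {
      cB <- cvec[basis]
      red <- cvec[allowed] -
        as.vector(crossprod(cB, Tb[, allowed, drop = FALSE]))
      ent <- allowed[red < -tol]
      if (!length(ent)) return("optimal")
      j <- min(ent)
      col <- Tb[, j]
      rows <- which(col > tol)
      if (!length(rows)) return("unbounded")
      ratios <- Tb[rows, rhs_col()] / col[rows]
      best <- min(ratios)
      cand <- rows[ratios <= best + 1e-12]
      i <- cand[which.min(basis[cand])]
      pivot_on(i, j)
    }
  }

  # phase 1: drive the artificial basis out
  c1 <- c(numeric(n), rep(1, m))
  st <- run_phase(c1, seq_len(n + m))
  stopifnot(st == "optimal")
  art_val <- sum(Tb[basis > n, rhs_col()])
  if (art_val > 1e-7) {
    return(list(status = "infeasible", objective = NA_real_, z = NULL))
  }
  # basic artificials sit at zero: pivot them out or drop redundant rows
  drop_rows <- integer(0)
  for (i in which(basis > n)) {
    j <- which(abs(Tb[i, seq_len(n)]) > tol)
    if (length(j)) pivot_on(i, min(j)) else drop_rows <- c(drop_rows, i)
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  c2 <- c(cost, numeric(m))
  st <- run_phase(c2, seq_len(n))
  if (st == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, z = NULL))
  }
  z <- numeric(n)
  keep <- basis <= n
  z[basis[keep]] <- Tb[keep, rhs_col()]
  obj <- sum(cost * z)
  list(status = "optimal", objective = if (maximize) -obj else obj, z = z)
}

oracle_solve <- function(model, objective, maximize = TRUE, extra = NULL) {
  rxn <- model$reactions
  n_all <- nrow(rxn)
  lb <- rxn$lower_bound
  ub <- rxn$upper_bound
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))

  met_ids <- model$metabolites$id
  A_full <- matrix(0, nrow = length(met_ids), ncol = n_all,
                   dimnames = list(met_ids, rxn$id))
  for (k in seq_len(n_all)) {
    s <- model$stoichiometry[[k]]
    for (met in names(s)) A_full[met, k] <- A_full[met, k] + s[[met]]
  }

  cc_full <- setNames(numeric(n_all), rxn$id)
  cc_full[names(objective)] <- as.numeric(objective)

  g_row_full <- NULL
  if (!is.null(extra)) {
    g_row_full <- setNames(numeric(n_all), rxn$id)
    g_row_full[names(extra$coeffs)] <- as.numeric(extra$coeffs)
  }

  # shift x = v - lb and eliminate variables fixed by lb == ub
  free <- which(ub - lb > 0)
  n <- length(free)
  const_obj <- sum(cc_full * lb)
  A <- A_full[, free, drop = FALSE]
  beq <- -as.vector(A_full %*% lb)
  cc <- cc_full[free]
  width <- ub[free] - lb[free]

  if (n == 0) {  # everything fixed: feasibility is a residual check
    g_ok <- if (is.null(extra)) TRUE else {
      lhs <- sum(g_row_full * lb)
      if (extra$dir == ">=") lhs >= extra$rhs - 1e-9 else lhs <= extra$rhs + 1e-9
    }
    return(if (max(abs(beq)) < 1e-9 && g_ok) {
      list(status = "optimal", objective = const_obj,
           fluxes = setNames(lb, rxn$id))
    } else list(status = "infeasible", objective = NA_real_))
  }

  # drop null balance rows; a nonzero rhs on one means plain infeasibility
  null_row <- apply(abs(A), 1, max) == 0
  if (any(null_row & abs(beq) > 1e-9)) {
    return(list(status = "infeasible", objective = NA_real_))
  }
  A <- A[!null_row, , drop = FALSE]
  beq <- beq[!null_row]
  m_bal <- nrow(A)

  # standard form: z = [x, s_ub, (s_gamma)] >= 0
  n_slack <- n + (!is.null(extra))
  M <- rbind(cbind(A, matrix(0, m_bal, n_slack)),
             cbind(diag(n), diag(n),
                   if (!is.null(extra)) matrix(0, n, 1)))
  rhs <- c(beq, width)
  if (!is.null(extra)) {
    srow <- c(g_row_full[free], numeric(n),
              if (extra$dir == ">=") -1 else 1)
    M <- rbind(M, srow, deparse.level = 0)
    rhs <- c(rhs, extra$rhs - sum(g_row_full * lb))
  }
  flip <- rhs < 0
  M[flip, ] <- -M[flip, ]
  rhs[flip] <- -rhs[flip]

  obj <- c(cc, numeric(n_slack))
  res <- oracle_simplex_std(M, rhs, obj, maximize = maximize)
  if (res$status != "optimal") {
    return(list(status = res$status, objective = NA_real_))
  }
  v <- lb
  v[free] <- res$z[seq_len(n)] + lb[free]
  list(status = "optimal",
       objective = res$objective + const_obj,
       fluxes = setNames(v, rxn$id))
}

oracle_fba <- function(model, objective = NULL, maximize = TRUE) {
  if (is.null(objective)) {
    k <- model$reactions$objective_coefficient != 0
    objective <- setNames(model$reactions$objective_coefficient[k],
                          model$reactions$id[k])
  }
  oracle_solve(model, objective, maximize = maximize)
}

# brute-force FVA: one independent min and max LP per reaction, the
# objective-fraction requirement passed as an explicit inequality row
oracle_fva <- function(model, gamma, reactions = model$reactions$id) {
  k <- model$reactions$objective_coefficient != 0
  obj <- setNames(model$reactions$objective_coefficient[k],
                  model$reactions$id[k])
  wt <- oracle_solve(model, obj, maximize = TRUE)
  stopifnot(wt$status == "optimal")
  extra <- list(coeffs = obj, rhs = gamma * wt$objective, dir = ">=")
  do.call(rbind, lapply(reactions, function(r) {
    lo <- oracle_solve(model, setNames(1, r), maximize = FALSE, extra = extra)
    hi <- oracle_solve(model, setNames(1, r), maximize = TRUE, extra = extra)
    data.frame(reaction = r, minimum = lo$objective, maximum = hi$objective,
               stringsAsFactors = FALSE)
  }))
}

# structural fields that define a model's scientific content
model_fields <- function(m) {
  m[c("id", "metabolites", "reactions", "stoichiometry", "genes")]
}

expect_model_equal <- function(a, b) {
  testthat::expect_identical(model_fields(a), model_fields(b))
}
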