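# Shared test oracles, kept independent of the code paths they check.

# Random flux network: integer stoichiometry, mixed reversibility.
# v = 0 is always feasible (lb <= 0 <= ub), so the LP has an optimum.
random_network <- function(n, m) {
  S <- matrix(sample(-2:2, m * n, replace = TRUE,
                     prob = c(0.1, 0.2, 0.4, 0.2, 0.1)), m, n)
  S <- S[rowSums(abs(S)) > 0, , drop = FALSE]
  list(
    S = S,
    lb = sample(c(-10, 0), n, replace = TRUE),
    ub = sample(c(5, 10), n, replace = TRUE),
    c = stats::rnorm(n) * stats::rbinom(n, 1, 0.5)
  )
}

# Independent LP oracle: scipy.optimize.linprog (HiGHS) through the
# system python, batched into a single subprocess call.  Solves
# max c'v  s.t.  S v = 0, lb <= v <= ub  for each instance and returns a
# data frame with status and objective.
lp_oracle_batch <- function(instances) {
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  payload <- lapply(instances, function(inst) {
    list(S = inst$S, lb = inst$lb, ub = inst$ub, c = inst$c)
  })
  jsonlite::write_json(payload, infile, digits = NA, matrix = "rowmajor")
  script <- '
import json, sys
import numpy as np
from scipy.optimize import linprog
with open(sys.argv[1]) as fh:
    instances = json.load(fh)
out = []
for inst in instances:
    S = np.atleast_2d(np.array(inst["S"], dtype=float))
    lb = np.array(inst["lb"], dtype=float)
    ub = np.array(inst["ub"], dtype=float)
    c = np.array(inst["c"], dtype=float)
    res = linprog(-c, A_eq=S, b_eq=np.zeros(S.shape[0]),
                  bounds=list(zip(lb, ub)), method="highs")
    status = {0: "optimal", 2: "infeasible", 3: "unbounded"}.get(
        res.status, "failed")
    out.append({"status": status,
                "objective": (-res.fun) if res.status == 0 else None})
with open(sys.argv[2], "w") as fh:
    json.dump(out, fh)
'
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  status <- system2("python", c(sf, infile, outfile),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(outfile)) {
    stop("LP oracle subprocess failed")
  }
  res <- jsonlite::fromJSON(outfile, simplifyDataFrame = TRUE)
  res$objective <- as.numeric(res$objective)
  res
}

# Uniform rejection sampler over {v : S v = 0, lb <= v <= ub}.  Proposals
# are uniform in a bounding box of the polytope expressed in an
# orthonormal null-space basis of S (box edges from per-coordinate LPs,
# inflated 1% for safety); acceptance checks only the box bounds, so the
# draw is exactly uniform on the polytope.  Slow but algorithmically
# unrelated to the hit-and-run chain it cross-checks.
rejection_sample_fluxes <- function(model, n_target, seed,
                                    batch = 200000L, max_batches = 200L) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  # reactions blocked at zero -- by their bounds (knockouts) or
  # stoichiometrically (FVA range collapses) -- are degenerate faces;
  # fold them into S as equalities so proposals live in the polytope's
  # own dimension
  fva <- generate_warmup(model)
  spread <- apply(fva, 2, function(col) max(col) - min(col))
  pinned <- which(spread < 1e-9 & abs(fva[1, ]) < 1e-9)
  if (length(pinned)) {
    E <- matrix(0, nrow = length(pinned), ncol = ncol(S))
    E[cbind(seq_along(pinned), pinned)] <- 1
    S <- rbind(S, E)
  }
  N <- kivflux:::nullspace_basis(S)
  d <- ncol(N)
  stopifnot(d >= 1)
  theta_rng <- t(vapply(seq_len(d), function(i) {
    lo <- kivflux:::lp_solve_bounded(S, rep(0, nrow(S)), -N[, i], lb, ub)
    hi <- kivflux:::lp_solve_bounded(S, rep(0, nrow(S)), N[, i], lb, ub)
    stopifnot(lo$status == "optimal", hi$status == "optimal")
    c(-lo$objective, hi$objective)
  }, numeric(2)))
  pad <- 0.01 * (theta_rng[, 2] - theta_rng[, 1])
  theta_rng[, 1] <- theta_rng[, 1] - pad
  theta_rng[, 2] <- theta_rng[, 2] + pad
  acc <- matrix(numeric(0), ncol = ncol(S))
  withr::with_seed(seed, {
    for (b in seq_len(max_batches)) {
      theta <- sapply(seq_len(d), function(i) {
        stats::runif(batch, theta_rng[i, 1], theta_rng[i, 2])
      })
      V <- theta %*% t(N)
      # 1e-9 slack absorbs the ~1e-16 null-space noise on pinned coords
      ok <- rowSums(sweep(V, 2, lb - 1e-9, `<`) |
                    sweep(V, 2, ub + 1e-9, `>`)) == 0
      acc <- rbind(acc, V[ok, , drop = FALSE])
      if (nrow(acc) >= n_target) break
    }
  })
  if (nrow(acc) < n_target) {
    stop("rejection sampler did not reach the target acceptance count")
  }
  colnames(acc) <- model$reactions$id
  acc[seq_len(n_target), , drop = FALSE]
}

# Worst steady-state residual and bound violation of a sample matrix.
sample_violations <- function(model, points) {
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  list(
    resid = max(abs(S %*% t(points))),
    bound = max(c(sweep(points, 2, ub) ,
                  sweep(-points, 2, -lb)))
  )
}
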