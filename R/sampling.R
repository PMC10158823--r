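# Monte Carlo sampling of the steady-state flux polytope
# {v : S v = 0, lb <= v <= ub} with the artificially-centered hit-and-run
# (ACHR) chain: directions are differences between a randomly chosen
# stored point and the running center, so the chain elongates along the
# polytope's long axes without an explicit rounding transform.

#' Warmup points for flux-cone sampling
#'
#' Computes the standard ACHR warmup set: for every reaction, the full
#' flux vectors attaining its FVA minimum and maximum (2n points, all
#' feasible vertices/faces of the polytope).
#'
#' @param model A [metabolic_model()].
#' @return A numeric matrix (2n x n) with reaction ids as column names.
#' @export
generate_warmup <- function(model) {
  rxns <- model$reactions$id
  n <- length(rxns)
  pts <- matrix(NA_real_, nrow = 2L * n, ncol = n,
                dimnames = list(NULL, rxns))
  for (j in seq_len(n)) {
    lo <- solve_fba(model, objective = rxns[j], sense = "min", zero_tol = 0)
    hi <- solve_fba(model, objective = rxns[j], sense = "max", zero_tol = 0)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("model is ", if (lo$status != "optimal") lo$status else hi$status,
           "; cannot generate warmup points", call. = FALSE)
    }
    pts[2L * j - 1L, ] <- lo$fluxes$flux
    pts[2L * j, ] <- hi$fluxes$flux
  }
  pts
}

# Orthonormal basis of the null space of S (directions preserving
# steady state), via SVD.
nullspace_basis <- function(S, tol = 1e-10) {
  if (nrow(S) == 0L) return(diag(1, ncol(S)))
  sv <- svd(S, nu = 0, nv = ncol(S))
  r <- sum(sv$d >= tol * max(sv$d[1], 1))
  if (r == ncol(S)) {
    matrix(0, nrow = ncol(S), ncol = 0)
  } else {
    sv$v[, seq(r + 1L, ncol(S)), drop = FALSE]
  }
}

#' Sample the flux polytope with artificially-centered hit-and-run
#'
#' Runs an ACHR chain over `{v : S v = 0, lb <= v <= ub}`: at each step a
#' stored point (warmup or previously kept sample) is drawn at random,
#' the direction is its difference from the running center, the step size
#' is uniform on the feasible segment through the current point, and the
#' center is updated incrementally.  Every `thinning`-th chain state is
#' recorded.  Accumulated drift off the steady-state subspace is removed
#' by projecting back onto the null space of S whenever the residual
#' exceeds 1e-9; reactions with `lb == ub` (e.g. knocked-out reactions)
#' are pinned to that value exactly.  Identical seeds give identical
#' output.
#'
#' @param model A [metabolic_model()].
#' @param n_points Number of samples to record (the study-scale default
#'   is 35000; use far fewer for desk work).
#' @param seed Integer seed (required; there is no wall-clock entropy).
#' @param thinning Chain steps per recorded sample (default 100).
#' @param warmup Optional warmup matrix from [generate_warmup()].
#' @return An object of class `sample_set`: list with `points`
#'   (`n_points` x n matrix, reaction ids as column names), `seed`,
#'   `thinning`, `n_warmup`.
#' @examples
#' toy <- make_toy_network()
#' s <- sample_achr(toy, n_points = 100, seed = 7, thinning = 10)
#' dim(s$points)
#' @export
sample_achr <- function(model, n_points = 35000, seed, thinning = 100,
                        warmup = NULL) {
  stopifnot(n_points >= 1, thinning >= 1)
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (is.null(warmup)) warmup <- generate_warmup(model)
  S <- stoich_matrix(model)
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  n <- ncol(S)
  fixed <- which(ub - lb < 1e-12)
  N <- nullspace_basis(S)
  project <- function(v) {
    # null space of S is linear (b = 0): orthogonal projection
    as.numeric(N %*% crossprod(N, v))
  }
  snap <- function(v) {
    if (length(fixed)) v[fixed] <- lb[fixed]
    pmin(pmax(v, lb), ub)
  }

  # a polytope that collapses to a single point (every reaction fixed by
  # the constraints) has exactly one feasible flux state: return it
  spread <- apply(warmup, 2, function(col) max(col) - min(col))
  if (max(spread) < 1e-12) {
    pts <- matrix(rep(snap(warmup[1, ]), each = n_points),
                  nrow = n_points, dimnames = list(NULL, colnames(warmup)))
    return(structure(
      list(points = pts, seed = seed, thinning = thinning,
           n_warmup = nrow(warmup), reactions = colnames(warmup)),
      class = "sample_set"
    ))
  }

  pool <- rbind(warmup,
                matrix(NA_real_, nrow = n_points, ncol = ncol(warmup)))
  n_pool <- nrow(warmup)
  local_seed(seed, {
    center <- colMeans(warmup)
    n_center <- nrow(warmup)
    x <- snap(center)
    points <- matrix(NA_real_, nrow = n_points, ncol = n,
                     dimnames = list(NULL, colnames(warmup)))
    kept <- 0L
    step <- 0L
    fails <- 0L
    while (kept < n_points) {
      step <- step + 1L
      idx <- sample.int(n_pool, 1L)
      d <- pool[idx, ] - center
      nd <- sqrt(sum(d^2))
      ok <- FALSE
      if (nd > 1e-12) {
        d <- d / nd
        move <- abs(d) > 1e-10
        amin <- -Inf
        amax <- Inf
        if (any(move)) {
          lo_r <- (lb[move] - x[move]) / d[move]
          hi_r <- (ub[move] - x[move]) / d[move]
          amin <- max(pmin(lo_r, hi_r))
          amax <- min(pmax(lo_r, hi_r))
        }
        if (is.finite(amin) && is.finite(amax) && amax - amin > 1e-12) {
          alpha <- stats::runif(1, amin, amax)
          x <- x + alpha * d
          if (max(abs(S %*% x)) > 1e-9) x <- project(x)
          x <- snap(x)
          ok <- TRUE
        }
      }
      if (!ok) {
        fails <- fails + 1L
        if (fails >= 1000L) {
          stop("flux polytope is numerically empty (no feasible segment ",
               "found in 1000 consecutive directions)", call. = FALSE)
        }
        next
      }
      fails <- 0L
      center <- (center * n_center + x) / (n_center + 1)
      n_center <- n_center + 1
      if (step %% thinning == 0L) {
        xr <- x
        if (max(abs(S %*% xr)) > 1e-9) xr <- snap(project(xr))
        kept <- kept + 1L
        points[kept, ] <- xr
        n_pool <- n_pool + 1L
        pool[n_pool, ] <- xr
      }
    }
    structure(
      list(points = points, seed = seed, thinning = thinning,
           n_warmup = nrow(warmup), reactions = colnames(warmup)),
      class = "sample_set"
    )
  })
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf(
    "<sample_set> %d points x %d reactions (seed %d, thinning %d, %d warmup)\n",
    nrow(x$points), ncol(x$points), x$seed, x$thinning, x$n_warmup))
  invisible(x)
}

#' Tidy a sample set into long format
#'
#' @param x A `sample_set`.
#' @param ... Unused.
#' @return A tibble with columns `sample`, `reaction`, `flux`.
#' @method tidy sample_set
#' @export
tidy.sample_set <- function(x, ...) {
  tibble::as_tibble(x$points) |>
    dplyr::mutate(sample = dplyr::row_number()) |>
    tidyr::pivot_longer(-sample, names_to = "reaction", values_to = "flux")
}

#' Per-reaction summaries of sampled fluxes
#'
#' For each requested reaction, computes the mean, median, 5th/95th
#' percentiles, and a normalized histogram over `n_bins` equal-width bins
#' spanning the observed range (a constant column occupies a single
#' degenerate bin).
#'
#' @param samples A `sample_set` from [sample_achr()].
#' @param reaction_ids Reactions to summarise (default: all sampled).
#' @param n_bins Number of histogram bins (default 50).
#' @return A tibble of class `flux_summary`: columns `reaction`, `mean`,
#'   `median`, `p5`, `p95`, `min`, `max` and `histogram` (list column of
#'   tibbles `bin_lo`, `bin_hi`, `frequency`; frequencies sum to 1).
#' @export
summarize_reaction_flux <- function(samples, reaction_ids = NULL,
                                    n_bins = 50) {
  stopifnot(inherits(samples, "sample_set"), n_bins >= 1)
  if (nrow(samples$points) == 0L) {
    stop("empty sample set", call. = FALSE)
  }
  if (is.null(reaction_ids)) reaction_ids <- samples$reactions
  unknown <- setdiff(reaction_ids, samples$reactions)
  if (length(unknown)) {
    stop("reaction(s) not in sample set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  rows <- purrr::map(reaction_ids, function(rid) {
    v <- samples$points[, rid]
    lo <- min(v)
    hi <- max(v)
    if (hi - lo < 1e-12) {
      histo <- tibble::tibble(bin_lo = lo, bin_hi = hi, frequency = 1)
    } else {
      edges <- seq(lo, hi, length.out = n_bins + 1L)
      counts <- tabulate(pmin(findInterval(v, edges, rightmost.closed = TRUE),
                              n_bins), nbins = n_bins)
      histo <- tibble::tibble(bin_lo = edges[-length(edges)],
                              bin_hi = edges[-1],
                              frequency = counts / sum(counts))
    }
    tibble::tibble(
      reaction = rid, mean = mean(v), median = stats::median(v),
      p5 = unname(stats::quantile(v, 0.05)),
      p95 = unname(stats::quantile(v, 0.95)),
      min = lo, max = hi, histogram = list(histo)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("flux_summary", class(out))
  out
}

#' Persist a sample set as a matrix file with a JSON sidecar
#'
#' Writes the points as CSV (one row per sample) plus `<path>.json`
#' recording seed, thinning, warmup size and reaction order, enough to
#' reproduce the chain.
#'
#' @param samples A `sample_set`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(samples, path) {
  utils::write.csv(as.data.frame(samples$points), path, row.names = FALSE)
  meta <- list(seed = samples$seed, thinning = samples$thinning,
               n_warmup = samples$n_warmup, reactions = samples$reactions,
               n_points = nrow(samples$points))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
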