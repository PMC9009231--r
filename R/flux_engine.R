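#' Flux balance analysis
#'
#' Maximizes the flux of an objective reaction subject to the steady-state
#' constraint `S v = 0` and the model's bounds, returning the optimum and
#' one optimal vertex.
#'
#' @param model a `metabolic_model`.
#' @param objective reaction id to maximize, or a named numeric vector of
#'   weights; defaults to the model's stored objective.
#' @param maximize logical.
#' @return a `flux_result`: list with `status` (`"optimal"`,
#'   `"infeasible"`, `"unbounded"`), `objective_value` and `fluxes` (named
#'   vector).
#' @export
fba <- function(model, objective = NULL, maximize = TRUE) {
  validate_model(model)
  S <- stoich_matrix(model)
  w <- .objective_weights(model, objective)
  res <- lp_solve(w, S, rep(0, nrow(S)), model$reactions$lower_bound,
                  model$reactions$upper_bound, maximize = maximize)
  if (res$status != "optimal") {
    return(structure(list(status = res$status, objective_value = NA_real_,
                          fluxes = NULL), class = "flux_result"))
  }
  structure(list(status = "optimal", objective_value = res$value,
                 fluxes = res$v), class = "flux_result")
}

.objective_weights <- function(model, objective) {
  rxid <- model$reactions$id
  if (is.null(objective)) {
    if (!length(model$objective)) stop("model has no objective")
    objective <- model$objective
  }
  if (is.character(objective)) {
    missing <- setdiff(objective, rxid)
    if (length(missing)) stop("unknown objective reaction(s): ",
                              paste(missing, collapse = ", "))
    objective <- stats::setNames(rep(1, length(objective)), objective)
  }
  w <- stats::setNames(rep(0, length(rxid)), rxid)
  w[names(objective)] <- objective
  w
}

#' @export
print.flux_result <- function(x, ...) {
  cat("<flux_result> status ", x$status,
      if (x$status == "optimal") paste0(", objective ",
                                        signif(x$objective_value, 6)),
      "\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Computes the minimum and maximum attainable flux of every reaction
#' subject to steady state and bounds, optionally with the model objective
#' held at a fraction of its optimum.
#'
#' @param model a `metabolic_model`.
#' @param objective_fraction optional value in (0, 1]; when given, adds
#'   the constraint `objective flux >= fraction * optimum`.
#' @param reactions reaction ids to analyze (default: all).
#' @return a `fva_result` data.frame with columns `reaction`, `min`, `max`.
#' @export
fva <- function(model, objective_fraction = NULL, reactions = NULL) {
  validate_model(model)
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  b <- rep(0, nrow(S))
  if (!is.null(objective_fraction)) {
    stopifnot(objective_fraction > 0, objective_fraction <= 1)
    w <- .objective_weights(model, NULL)
    opt <- fba(model)
    if (opt$status != "optimal") stop("FVA: model is ", opt$status)
    # w'v - s = f*opt with slack s >= 0 turns the floor into an equality
    S <- rbind(cbind(S, 0), c(w, -1))
    b <- c(b, objective_fraction * opt$objective_value)
    smax <- sum(pmax(w * ub, w * lb)) - objective_fraction *
      opt$objective_value
    lb <- c(lb, 0); ub <- c(ub, max(smax, 0))
  }
  ids <- if (is.null(reactions)) model$reactions$id else reactions
  n <- ncol(S)
  out <- data.frame(reaction = ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    j <- match(ids[k], model$reactions$id)
    obj <- rep(0, n); obj[j] <- 1
    lo <- lp_solve(obj, S, b, lb, ub, maximize = FALSE)
    hi <- lp_solve(obj, S, b, lb, ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA: solve for reaction '", ids[k], "' returned ",
           lo$status, "/", hi$status)
    }
    out$min[k] <- lo$value
    out$max[k] <- hi$value
  }
  class(out) <- c("fva_result", "data.frame")
  out
}

#' Remove reactions that cannot carry flux
#'
#' Drops every reaction whose FVA range is contained in `[-tol, tol]`,
#' along with metabolites left unreferenced; the result is the per-sample
#' "individual model". Pruning cannot change any attainable flux
#' distribution, so the FBA optimum is preserved.
#'
#' @param model a `metabolic_model`.
#' @param fva_result result of [fva()] on this model.
#' @param tol zero-flux tolerance (mmol/L/min).
#' @return a pruned `metabolic_model`.
#' @export
prune_zero_flux <- function(model, fva_result, tol = 1e-6) {
  stopifnot(inherits(fva_result, "fva_result"))
  blocked <- abs(fva_result$min) <= tol & abs(fva_result$max) <= tol
  keep <- setdiff(model$reactions$id, fva_result$reaction[blocked])
  subset_model(model, keep)
}

#' Sample the steady-state flux polytope by artificial-centering
#' hit-and-run
#'
#' Generates warmup vertices by optimizing random objective directions
#' (alternating maximize/minimize), then walks through the polytope: each
#' step picks a direction from a stored point through the running center,
#' computes the feasible segment allowed by the bounds, and jumps to a
#' uniform point on it. Every `thinning`-th point is recorded. Directions
#' are differences of steady-state points, so `S v = 0` is preserved
#' exactly along the walk.
#'
#' @param model a feasible `metabolic_model`.
#' @param n_draws number of recorded draws.
#' @param warmup number of warmup vertices.
#' @param thinning record every `thinning`-th step.
#' @param seed integer seed; fixed seed reproduces the matrix exactly.
#' @return a `flux_samples` object: list with `points` (reactions x draws
#'   matrix), `seed`, `warmup`, `thinning`.
#' @export
achr_sample <- function(model, n_draws = 1000, warmup = 200, thinning = 100,
                        seed = 1) {
  validate_model(model)
  S <- stoich_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  set.seed(seed)
  W <- matrix(NA_real_, n, warmup)
  for (k in seq_len(warmup)) {
    obj <- stats::rnorm(n)
    res <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub,
                    maximize = (k %% 2L == 0L))
    if (res$status != "optimal") {
      stop("ACHR warmup: model is ", res$status)
    }
    W[, k] <- res$v
  }
  if (max(apply(W, 1, function(r) diff(range(r)))) < 1e-12) {
    warning("flux polytope is a single point; returning it replicated")
    pts <- matrix(W[, 1], n, n_draws,
                  dimnames = list(model$reactions$id, NULL))
    return(structure(list(points = pts, seed = seed, warmup = warmup,
                          thinning = thinning), class = "flux_samples"))
  }
  center <- rowMeans(W)
  x <- W[, 1]
  npts <- warmup
  pts <- matrix(NA_real_, n, n_draws,
                dimnames = list(model$reactions$id, NULL))
  recorded <- 0L
  step <- 0L
  while (recorded < n_draws) {
    step <- step + 1L
    u <- W[, sample.int(warmup, 1L)] - center
    nu <- sqrt(sum(u * u))
    if (nu < 1e-12) next
    u <- u / nu
    # feasible segment: lb <= x + a*u <= ub
    amin <- -Inf; amax <- Inf
    pos <- u > 1e-11; neg <- u < -1e-11
    if (any(pos)) {
      amax <- min(amax, min((ub[pos] - x[pos]) / u[pos]))
      amin <- max(amin, max((lb[pos] - x[pos]) / u[pos]))
    }
    if (any(neg)) {
      amax <- min(amax, min((lb[neg] - x[neg]) / u[neg]))
      amin <- max(amin, max((ub[neg] - x[neg]) / u[neg]))
    }
    if (!is.finite(amin) || !is.finite(amax) || amax < amin) next
    a <- stats::runif(1, amin, amax)
    x <- pmin(pmax(x + a * u, lb), ub)
    center <- (center * npts + x) / (npts + 1)
    npts <- npts + 1
    if (step %% thinning == 0L) {
      recorded <- recorded + 1L
      pts[, recorded] <- x
    }
  }
  structure(list(points = pts, seed = seed, warmup = warmup,
                 thinning = thinning), class = "flux_samples")
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("<flux_samples> ", nrow(x$points), " reactions x ", ncol(x$points),
      " draws (seed ", x$seed, ", warmup ", x$warmup, ", thinning ",
      x$thinning, ")\n", sep = "")
  invisible(x)
}

#' Summarize sampled fluxes into a reaction x sample mean-flux matrix
#'
#' Averages the draws of each per-sample model. Rows are the union of
#' reactions over samples; a reaction pruned from one sample's model
#' contributes 0 in that column, so cohort matrices are rectangular.
#'
#' @param samples named list of `flux_samples`, one per sample.
#' @return numeric matrix, union-of-reactions x samples.
#' @export
summarize_samples <- function(samples) {
  stopifnot(length(samples) >= 1L)
  if (is.null(names(samples))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  all_rxn <- unique(unlist(lapply(samples, function(s) rownames(s$points))))
  out <- matrix(0, length(all_rxn), length(samples),
                dimnames = list(all_rxn, names(samples)))
  for (s in names(samples)) {
    mn <- rowMeans(samples[[s]]$points)
    out[names(mn), s] <- mn
  }
  out
}
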