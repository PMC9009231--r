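#' Reduce a model to its kinetically covered core (GIMME-style)
#'
#' Keeps the largest sub-network that favours reactions with turnover
#' (Kcat) records while preserving stated objectives. For each objective,
#' a linear program minimizes the total absolute flux through penalized
#' reactions (those without a Kcat record) subject to steady state, the
#' model bounds, and the objective held at `fraction` of its optimum;
#' absolute values are handled by the standard flux split into positive
#' and negative parts. The reduced model is the union over objectives of
#' every Kcat-covered reaction plus every penalized reaction that carries
#' flux above `tol` in a minimizing solution. Because the full support of
#' each minimizing solution is retained, every objective remains
#' attainable at `>= fraction * optimum` in the reduced model.
#'
#' @param model a `metabolic_model`.
#' @param kcats a `kcat_table`; a reaction is covered when
#'   [kcat_lookup()] finds a record for it.
#' @param objectives character vector of objective reaction ids; defaults
#'   to the model's stored objective (the convention is ATP production
#'   plus biomass).
#' @param fraction required objective fraction in (0, 1]; 0.9 is the
#'   customary setting.
#' @param tol flux tolerance above which a penalized reaction counts as
#'   carrying flux (mmol/L/min).
#' @param penalty optional named 0/1 vector overriding the Kcat-derived
#'   penalty indicator (1 = penalized). This admits the
#'   expression-threshold variant: penalize reactions whose expression
#'   falls below a cutoff instead of reactions without Kcat records.
#' @return the reduced, revalidated `metabolic_model`.
#' @export
gimme_reduce <- function(model, kcats, objectives = NULL, fraction = 0.9,
                         tol = 1e-6, penalty = NULL) {
  validate_model(model)
  stopifnot(fraction > 0, fraction <= 1)
  rx <- model$reactions
  if (is.null(objectives)) {
    if (!length(model$objective)) stop("model has no objective")
    objectives <- names(model$objective)
  }
  missing_obj <- setdiff(objectives, rx$id)
  if (length(missing_obj)) {
    stop("objective reaction(s) not in model: ",
         paste(missing_obj, collapse = ", "))
  }
  if (is.null(penalty)) {
    penalty <- vapply(seq_len(nrow(rx)), function(j) {
      as.numeric(is.na(kcat_lookup(kcats, rx$id[j], rx$ec[j])))
    }, numeric(1))
    names(penalty) <- rx$id
  } else {
    penalty <- penalty[rx$id]
    penalty[is.na(penalty)] <- 0
  }
  S <- stoich_matrix(model)
  lb <- rx$lower_bound; ub <- rx$upper_bound
  n <- nrow(rx)
  keep <- rx$id[penalty == 0]
  for (o in objectives) {
    opt <- fba(model, objective = o)
    if (opt$status != "optimal" || opt$objective_value <= tol) {
      stop("objective '", o, "' is ",
           if (opt$status != "optimal") opt$status else "zero at optimum")
    }
    floor_o <- fraction * opt$objective_value
    # split penalized reversible reactions: v_j = v_j^+ - v_j^-
    split_idx <- which(penalty == 1 & lb < 0)
    ns <- length(split_idx)
    # columns: n original + ns negative parts + 1 slack for objective floor
    A <- cbind(S, -S[, split_idx, drop = FALSE], 0)
    wobj <- as.numeric(rx$id == o)
    A <- rbind(A, c(wobj, rep(0, ns), -1))
    b <- c(rep(0, nrow(S)), floor_o)
    lo <- c(pmax(lb, 0) * (penalty == 1) + lb * (penalty == 0),
            rep(0, ns), 0)
    # penalized split columns: original column holds the positive part
    lo[split_idx] <- 0
    hi <- c(ub, -lb[split_idx], sum(pmax(wobj * ub, wobj * lb)))
    cost <- c(penalty, rep(1, ns), 0)
    res <- lp_solve(cost, A, b, lo, hi, maximize = FALSE)
    if (res$status != "optimal") {
      stop("reduction LP for objective '", o, "' returned ", res$status)
    }
    vpos <- res$v[seq_len(n)]
    v <- vpos
    if (ns) v[split_idx] <- vpos[split_idx] - res$v[n + seq_len(ns)]
    keep <- union(keep, rx$id[penalty == 1 & abs(v) > tol])
  }
  reduced <- subset_model(model, keep)
  reduced$objective <- model$objective[names(model$objective) %in%
                                         reduced$reactions$id]
  reduced
}

#' Summarize a model reduction
#'
#' Reports what survived: metabolite/reaction/gene retention, the
#' per-component reaction breakdown, and the fraction of enzymatic
#' reactions lacking a Kcat record in the reduced model.
#'
#' @param before,after the models before and after reduction; `after`
#'   must be a sub-model of `before`.
#' @param kcats the `kcat_table` used for the reduction.
#' @return a list with `counts` (data.frame of before/after/retained for
#'   metabolites, reactions, genes), `components` (reaction counts by
#'   functional component, before vs after), and
#'   `enzymatic_without_kcat` (count and fraction in `after`).
#' @export
reduction_report <- function(before, after, kcats) {
  if (!all(after$reactions$id %in% before$reactions$id)) {
    stop("'after' is not a sub-model of 'before'")
  }
  counts <- data.frame(
    what = c("metabolites", "reactions", "genes"),
    before = c(nrow(before$metabolites), nrow(before$reactions),
               length(before$genes)),
    after = c(nrow(after$metabolites), nrow(after$reactions),
              length(after$genes)))
  counts$retained <- counts$after / counts$before
  comp_b <- table(classify_reactions(before))
  comp_a <- table(classify_reactions(after))
  labels <- union(names(comp_b), names(comp_a))
  components <- data.frame(
    component = labels,
    before = as.integer(comp_b[labels]),
    after = as.integer(comp_a[labels]))
  components[is.na(components)] <- 0L
  rx <- after$reactions
  enz <- classify_reactions(after) == "enzymatic"
  nokcat <- vapply(seq_len(nrow(rx)), function(j) {
    enz[j] && is.na(kcat_lookup(kcats, rx$id[j], rx$ec[j]))
  }, logical(1))
  list(counts = counts, components = components,
       enzymatic_without_kcat = list(
         n = sum(nokcat),
         fraction = if (any(enz)) sum(nokcat) / sum(enz) else NA_real_))
}
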