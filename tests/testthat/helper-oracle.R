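# Brute-force LP oracle: enumerate vertices of {v : S v = 0, lb <= v <= ub}
# in null-space coordinates and take the best objective value. Independent
# of the simplex implementation under test.
lp_oracle <- function(obj, S, lb, ub, maximize = TRUE) {
  N <- MASS::Null(t(S))
  d <- ncol(N)
  if (d == 0) return(0)
  A <- rbind(N, -N)
  b <- c(ub, -lb)
  best <- NULL
  idx <- utils::combn(nrow(A), d)
  for (j in seq_len(ncol(idx))) {
    Ai <- A[idx[, j], , drop = FALSE]
    if (abs(det(Ai)) < 1e-10) next
    t0 <- solve(Ai, b[idx[, j]])
    if (all(A %*% t0 <= b + 1e-8)) {
      val <- sum(obj * (N %*% t0))
      if (is.null(best) || (maximize && val > best) ||
          (!maximize && val < best)) {
        best <- val
      }
    }
  }
  best
}

fba_oracle <- function(model, objective, maximize = TRUE) {
  S <- stoich_matrix(model)
  obj <- as.numeric(model$reactions$id == objective)
  lp_oracle(obj, S, model$reactions$lower_bound,
            model$reactions$upper_bound, maximize = maximize)
}

fva_oracle <- function(model) {
  ids <- model$reactions$id
  data.frame(
    reaction = ids,
    min = vapply(ids, function(r) fba_oracle(model, r, FALSE), numeric(1)),
    max = vapply(ids, function(r) fba_oracle(model, r, TRUE), numeric(1)))
}

# directed linear chain A_ex -> A -> B -> B_ex with an uptake cap
make_directed_chain <- function(uptake = 5) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(id = c("EX_A", "AB", "EX_B"),
                   lower_bound = c(-uptake, 0, 0),
                   upper_bound = c(0, 1000, 1000),
                   stringsAsFactors = FALSE)
  rx$stoichiometry <- list(c(A = -1), c(A = -1, B = 1), c(B = -1))
  metabolic_model(mets, rx)
}
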