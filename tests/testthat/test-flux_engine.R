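toy <- make_toy_model()

test_that("FBA on the toy network matches the vertex-enumeration oracle", {
  r <- fba(toy$model)
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_value, 80)  # 2 glc respired (O2-limited) + 8 fermented
  expect_equal(r$objective_value, fba_oracle(toy$model, "ATPM"),
               tolerance = 1e-9)
  # optimal vertex is feasible
  S <- stoich_matrix(toy$model)
  expect_lt(max(abs(S %*% r$fluxes)), 1e-9)
})

test_that("FBA handles closed and inconsistent models", {
  m <- toy$model
  m$reactions$lower_bound[grepl("^EX_", m$reactions$id)] <- 0
  m$reactions$reversible <- m$reactions$lower_bound < 0
  expect_equal(fba(m)$objective_value, 0)
  bad <- toy$model
  bad$reactions$lower_bound[1] <- 5
  bad$reactions$upper_bound[1] <- -5
  expect_error(fba(bad), "lower_bound > upper_bound")
})

test_that("FVA matches the oracle and finds blocked reactions", {
  fv <- fva(toy$model)
  orc <- fva_oracle(toy$model)
  expect_equal(fv$min, orc$min, tolerance = 1e-9)
  expect_equal(fv$max, orc$max, tolerance = 1e-9)
  expect_equal(fv$max[fv$reaction == "EX_glc"], 0)
  expect_equal(fv$min[fv$reaction == "EX_glc"], -10)
  # interior reactions of a directed chain carry (0, uptake)
  chain <- make_directed_chain(uptake = 5)
  fvc <- fva(chain)
  expect_equal(fvc$min[fvc$reaction == "AB"], 0, tolerance = 1e-9)
  expect_equal(fvc$max[fvc$reaction == "AB"], 5, tolerance = 1e-9)
  # dead-end reaction (product never consumed, no exchange) is blocked
  m <- add_reaction(toy$model, "DEAD", c(glc_c = -1, dead_c = 1))
  fvd <- fva(m)
  expect_equal(fvd$min[fvd$reaction == "DEAD"], 0, tolerance = 1e-9)
  expect_equal(fvd$max[fvd$reaction == "DEAD"], 0, tolerance = 1e-9)
})

test_that("FVA honours an objective-fraction floor", {
  fv <- fva(toy$model, objective_fraction = 1)
  # at the full optimum respiration is pinned at 2 and fermentation at 8
  expect_equal(fv$min[fv$reaction == "RESP"], 2, tolerance = 1e-6)
  expect_equal(fv$max[fv$reaction == "RESP"], 2, tolerance = 1e-6)
})

test_that("pruning removes blocked reactions and preserves the optimum", {
  m <- add_reaction(toy$model, "DEAD", c(glc_c = -1, dead_c = 1))
  before <- fba(m)$objective_value
  pruned <- prune_zero_flux(m, fva(m))
  expect_false("DEAD" %in% pruned$reactions$id)
  expect_false("dead_c" %in% pruned$metabolites$id)
  expect_equal(fba(pruned)$objective_value, before, tolerance = 1e-9)
  # FVA ranges of surviving reactions are unchanged
  fv_before <- fva(m)
  fv_after <- fva(pruned)
  shared <- fv_after$reaction
  expect_equal(fv_after$min, fv_before$min[match(shared, fv_before$reaction)],
               tolerance = 1e-6)
  expect_equal(fv_after$max, fv_before$max[match(shared, fv_before$reaction)],
               tolerance = 1e-6)
  # nothing blocked -> identity
  pruned2 <- prune_zero_flux(pruned, fva(pruned))
  expect_equal(pruned2$reactions$id, pruned$reactions$id)
})

test_that("ACHR draws are feasible, seed-deterministic and fill the polytope", {
  s <- achr_sample(toy$model, n_draws = 200, warmup = 40, thinning = 5,
                   seed = 9)
  S <- stoich_matrix(toy$model)
  expect_lt(max(abs(S %*% s$points)), 1e-6)
  lb <- toy$model$reactions$lower_bound
  ub <- toy$model$reactions$upper_bound
  expect_true(all(s$points >= lb - 1e-9))
  expect_true(all(s$points <= ub + 1e-9))
  s2 <- achr_sample(toy$model, n_draws = 200, warmup = 40, thinning = 5,
                    seed = 9)
  expect_identical(s$points, s2$points)
  s3 <- achr_sample(toy$model, n_draws = 200, warmup = 40, thinning = 5,
                    seed = 10)
  expect_false(identical(s$points, s3$points))
})

test_that("ACHR reproduces the uniform law on a 1-D polytope", {
  m <- make_chain_model(bound = 1)
  s <- achr_sample(m, n_draws = 5000, warmup = 50, thinning = 2, seed = 3)
  v <- s$points["AB", ]
  # mean near 0 (uniform on [-1, 1]); allowance covers the walk's
  # residual autocorrelation on top of the iid standard error
  expect_lt(abs(mean(v)), 0.05)
  ks <- suppressWarnings(stats::ks.test(v, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("a degenerate single-point polytope is returned replicated", {
  chain <- make_directed_chain(uptake = 5)
  # force exactly 5 through the chain: a single feasible point
  chain$reactions$lower_bound[chain$reactions$id == "EX_A"] <- -5
  chain$reactions$upper_bound[chain$reactions$id == "EX_A"] <- -5
  expect_warning(s <- achr_sample(chain, n_draws = 10, warmup = 10,
                                  thinning = 2, seed = 1),
                 "single point")
  expect_equal(ncol(s$points), 10)
  expect_equal(max(apply(s$points, 1, sd)), 0)
})

test_that("sample summaries align reactions across pruned models", {
  p1 <- matrix(1:6 / 10, 3, 2,
               dimnames = list(c("R1", "R2", "R3"), NULL))
  p2 <- matrix(rep(2, 4), 2, 2, dimnames = list(c("R1", "R4"), NULL))
  sm <- summarize_samples(list(
    A = structure(list(points = p1), class = "flux_samples"),
    B = structure(list(points = p2), class = "flux_samples")))
  expect_equal(dim(sm), c(4L, 2L))
  expect_equal(sm["R2", "A"], mean(p1["R2", ]))
  expect_equal(sm["R2", "B"], 0)   # pruned from B contributes zero
  expect_equal(sm["R4", "B"], 2)
})
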