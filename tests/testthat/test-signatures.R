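co <- make_synthetic_cohort(seed = 5, effect = 1.5)

test_that("model 1 recovers a planted group shift and is calibrated under the null", {
  f1 <- fit_model1(co$matrix, co$design, "CEN", "F1SP")
  planted <- co$truth$planted_features
  hit <- f1$feature %in% planted & f1$beta > 0 & f1$p < 0.01
  expect_gte(sum(hit), 18)  # >= 18 of the 20 planted features
  # permuted labels: ~5% of null features significant at 0.05
  d2 <- co$design
  set.seed(99)
  d2$group <- sample(d2$group)
  f_null <- fit_model1(co$matrix, d2, "CEN", "F1SP")
  frac <- mean(f_null$p < 0.05)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
  # constant features are excluded with notice
  m2 <- co$matrix
  m2[1, ] <- 7
  f_c <- fit_model1(m2, co$design, "CEN", "F1SP")
  expect_false(rownames(m2)[1] %in% f_c$feature)
  expect_true(rownames(m2)[1] %in% attr(f_c, "excluded"))
  expect_error(fit_model1(co$matrix, co$design, "CEN", "GHOST"),
               "both groups")
})

test_that("model 1 agrees with lm() feature by feature", {
  f1 <- fit_model1(co$matrix, co$design, "CEN", "F1SP")
  for (feat in sample(f1$feature, 5)) {
    d <- co$design
    d$y <- co$matrix[feat, d$sample]
    d$grp <- as.numeric(d$group == "CEN")
    d$male <- as.numeric(d$sex == "male")
    ref <- summary(lm(y ~ grp + male, data = d))$coefficients
    expect_equal(f1$beta[f1$feature == feat], ref["grp", 1],
                 tolerance = 1e-10)
    expect_equal(f1$p[f1$feature == feat], ref["grp", 4],
                 tolerance = 1e-10)
  }
})

test_that("model 2 recovers a planted age slope within controls", {
  co2 <- make_synthetic_cohort(seed = 8, effect = 1.0, aging_frac = 0.2,
                               aging_slope = 0.05)
  f2 <- fit_model2(co2$matrix, co2$design, "F1SP")
  aging <- co2$truth$aging_features
  hit <- f2$feature %in% aging & f2$beta > 0 & f2$p < 0.05
  expect_gte(sum(hit) / length(aging), 0.8)
  frac_null <- mean(f2$p[!f2$feature %in% aging] < 0.05)
  expect_lte(frac_null, 0.12)
  # degenerate age vector is rejected
  d <- co2$design
  d$age <- 60
  expect_error(fit_model2(co2$matrix, d, "F1SP"), "distinct ages")
})

test_that("signature calls implement the dual-model exclusion rule", {
  mk <- function(beta, p, tag) {
    out <- data.frame(feature = "f", beta = beta, p = p)
    class(out) <- c("model_fit", "data.frame")
    out
  }
  call1 <- function(b1, p1, b2, p2) {
    call_signature(mk(b1, p1), mk(b2, p2))$call
  }
  expect_equal(call1(+1, 0.01, +1, 0.5), "up")
  expect_equal(call1(+1, 0.01, +1, 0.01), "none")  # aging explains it
  expect_equal(call1(+1, 0.01, -1, 0.01), "up")    # opposite-sign aging ok
  expect_equal(call1(+1, 0.2, +1, 0.5), "none")
  expect_equal(call1(-1, 0.01, +1, 0.5), "down")
  expect_equal(call1(-1, 0.01, -1, 0.01), "none")
  # up + down + none partitions the features
  f1 <- fit_model1(co$matrix, co$design, "CEN", "F1SP")
  f2 <- fit_model2(co$matrix, co$design, "F1SP")
  sig <- call_signature(f1, f2)
  expect_equal(sum(sig$call == "up") + sum(sig$call == "down") +
                 sum(sig$call == "none"), nrow(sig))
})

test_that("DA scores follow (up - down) / total", {
  sig <- data.frame(
    feature = sprintf("f%02d", 1:10),
    call = c(rep("up", 4), "down", rep("none", 5)))
  class(sig) <- c("signature_result", "data.frame")
  grouping <- data.frame(feature = sig$feature, subsystem = "S")
  expect_equal(da_score(sig, grouping)$da, 0.3)
  sig$call <- "up"
  expect_equal(da_score(sig, grouping)$da, 1.0)
  sig$call <- "none"
  expect_equal(da_score(sig, grouping)$da, 0.0)
  # empty subsystems are omitted
  grouping2 <- rbind(grouping,
                     data.frame(feature = "absent", subsystem = "EMPTY"))
  expect_false("EMPTY" %in% da_score(sig, grouping2)$subsystem)
})

test_that("label-shuffle bootstrap flags the planted subsystem only", {
  da <- da_bootstrap(co$matrix, co$design, co$grouping, "CEN", "F1SP",
                     B = 500, seed = 11)
  planted <- co$truth$planted_subsystem
  expect_gt(da$da[da$subsystem == planted], 0.5)
  expect_lt(da$fdr[da$subsystem == planted], 0.05)
  # DA = 0 gets p = 1 by convention
  expect_true(all(da$p[da$da == 0] == 1))
  # deterministic under a fixed seed
  da2 <- da_bootstrap(co$matrix, co$design, co$grouping, "CEN", "F1SP",
                      B = 500, seed = 11)
  expect_identical(da, da2)
  expect_warning(da_bootstrap(co$matrix, co$design, co$grouping, "CEN",
                              "F1SP", B = 50, seed = 1), "coarse")
})

test_that("Welch t from summaries matches a full-data Welch test", {
  # construct raw samples with exactly the stated summaries
  mk <- function(n, m, s) as.numeric(scale(rnorm(n))) * s + m
  set.seed(2)
  x <- mk(76, 146.0, 20.1)
  y <- mk(41, 137.9, 18.0)
  ref <- t.test(x, y)
  got <- welch_t_from_summary(146.0, 20.1, 76, 137.9, 18.0, 41)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  # identical summaries: t = 0, p = 1
  same <- welch_t_from_summary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("Fisher exact handles enumerable and degenerate tables", {
  # margins (2,2)x(2,2): three tables with probs 1/6, 4/6, 1/6
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)),
                 "zero margin")
  expect_equal(p0, 1)
})

test_that("signature correlation matches a direct correlation oracle", {
  f1 <- fit_model1(co$matrix, co$design, "CEN", "F1SP")
  expect_equal(compare_signatures(f1, f1)$r, 1)
  f_neg <- f1
  f_neg$beta <- -f_neg$beta
  expect_equal(compare_signatures(f1, f_neg)$r, -1)
  set.seed(4)
  fa <- f1; fa$beta <- rnorm(nrow(fa))
  fb <- f1; fb$beta <- rnorm(nrow(fb))
  got <- compare_signatures(fa, fb)
  expect_equal(got$r, cor(fa$beta, fb$beta), tolerance = 1e-12)
  expect_error(compare_signatures(fa[1:2, ], fb[1:2, ]), "3 shared")
})
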