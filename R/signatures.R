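# Dual-linear-model signature engine: model 1 contrasts case vs control
# (adjusted for sex) to give the unfiltered case signature; model 2
# regresses on age within controls to give the aging effect; calls keep
# the case signal that the aging effect does not explain. Subsystem-level
# differential-abundance (DA) scores are tested by shuffling group labels.

# least squares of each column of Y on X; returns beta and two-sided p of
# column `term`. Drops the sex column if it is constant in the subset.
.lm_beta_p <- function(Y, X, term) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    if (ncol(X) == 3L && term == 2L) {
      X <- X[, 1:2, drop = FALSE]
      qx <- qr(X)
    }
    if (qx$rank < ncol(X)) {
      stop("design matrix is rank deficient (degenerate covariate)")
    }
  }
  n <- nrow(X); k <- ncol(X)
  coefs <- qr.coef(qx, Y)
  res <- Y - X %*% coefs
  df <- n - k
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtx_inv[term, term])
  beta <- coefs[term, ]
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  p[se == 0] <- NA_real_
  list(beta = as.numeric(beta), p = as.numeric(p), df = df)
}

.design_subset <- function(mat, design, groups) {
  d <- design[design$group %in% groups, , drop = FALSE]
  d <- d[d$sample %in% colnames(mat), , drop = FALSE]
  d
}

#' Fit model 1: the unfiltered case-group signature
#'
#' Per feature, ordinary least squares of abundance on a case-group
#' indicator plus a sex indicator, over the case and control samples:
#' `value ~ group + sex`. The group beta and its two-sided p-value make
#' up the unfiltered signature; aging-driven features are filtered out
#' later against [fit_model2()].
#'
#' @param mat feature x sample numeric matrix.
#' @param design data.frame with columns `sample`, `group`, `age`, `sex`.
#' @param case,control group labels (case coded 1).
#' @return a `model_fit` data.frame (`feature`, `beta`, `p`) with
#'   attributes `model = "model1"` and `excluded` (zero-variance feature
#'   ids, which are not fitted).
#' @export
fit_model1 <- function(mat, design, case, control) {
  d <- .design_subset(mat, design, c(case, control))
  if (!any(d$group == case) || !any(d$group == control)) {
    stop("both groups must be present: ", case, " n=",
         sum(d$group == case), ", ", control, " n=",
         sum(d$group == control))
  }
  Y <- t(mat[, d$sample, drop = FALSE])
  keep <- apply(Y, 2, stats::sd) > 0
  X <- cbind(1, as.numeric(d$group == case), as.numeric(d$sex == "male"))
  fit <- .lm_beta_p(Y[, keep, drop = FALSE], X, term = 2L)
  out <- data.frame(feature = colnames(Y)[keep], beta = fit$beta,
                    p = fit$p, stringsAsFactors = FALSE)
  attr(out, "model") <- "model1"
  attr(out, "excluded") <- colnames(Y)[!keep]
  class(out) <- c("model_fit", "data.frame")
  out
}

#' Fit model 2: the aging effect within controls
#'
#' Per feature, ordinary least squares of abundance on age plus a sex
#' indicator, within the control group only: `value ~ age + sex`.
#'
#' @inheritParams fit_model1
#' @param control control-group label; needs at least 3 distinct ages.
#' @return a `model_fit` data.frame as in [fit_model1()], with
#'   `model = "model2"`.
#' @export
fit_model2 <- function(mat, design, control) {
  d <- .design_subset(mat, design, control)
  if (length(unique(d$age)) < 3L) {
    stop("control group needs >= 3 distinct ages, found ",
         length(unique(d$age)))
  }
  Y <- t(mat[, d$sample, drop = FALSE])
  keep <- apply(Y, 2, stats::sd) > 0
  X <- cbind(1, d$age, as.numeric(d$sex == "male"))
  fit <- .lm_beta_p(Y[, keep, drop = FALSE], X, term = 2L)
  out <- data.frame(feature = colnames(Y)[keep], beta = fit$beta,
                    p = fit$p, stringsAsFactors = FALSE)
  attr(out, "model") <- "model2"
  attr(out, "excluded") <- colnames(Y)[!keep]
  class(out) <- c("model_fit", "data.frame")
  out
}

#' Call per-feature signatures from the dual fits
#'
#' A feature is `up` when model 1 finds a significant positive group
#' effect (`p < alpha`, `beta > 0`) that model 2 does not attribute to
#' aging in the same direction (model 2 not significant, or negative);
#' `down` is the mirror image; everything else is `none`.
#'
#' @param fit1,fit2 `model_fit` objects sharing feature ids.
#' @param alpha significance level for both models.
#' @return a `signature_result` data.frame: `feature`, `beta1`, `p1`,
#'   `beta2`, `p2`, `call`.
#' @export
call_signature <- function(fit1, fit2, alpha = 0.05) {
  shared <- intersect(fit1$feature, fit2$feature)
  i1 <- match(shared, fit1$feature)
  i2 <- match(shared, fit2$feature)
  out <- data.frame(feature = shared,
                    beta1 = fit1$beta[i1], p1 = fit1$p[i1],
                    beta2 = fit2$beta[i2], p2 = fit2$p[i2],
                    stringsAsFactors = FALSE)
  out$call <- .call_rule(out$beta1, out$p1, out$beta2, out$p2, alpha)
  class(out) <- c("signature_result", "data.frame")
  out
}

.call_rule <- function(beta1, p1, beta2, p2, alpha) {
  aging_up <- p2 < alpha & beta2 > 0
  aging_down <- p2 < alpha & beta2 < 0
  up <- p1 < alpha & beta1 > 0 & !aging_up
  down <- p1 < alpha & beta1 < 0 & !aging_down
  ifelse(up, "up", ifelse(down, "down", "none"))
}

#' Differential-abundance score per subsystem
#'
#' `DA = (#up - #down) / #features` within each subsystem, in `[-1, 1]`.
#' Subsystems with no feature in the signature are omitted.
#'
#' @param signature a `signature_result`.
#' @param grouping data.frame with columns `feature`, `subsystem` (each
#'   feature mapped to at most one subsystem).
#' @return data.frame: `subsystem`, `n`, `up`, `down`, `da`.
#' @export
da_score <- function(signature, grouping) {
  g <- grouping[grouping$feature %in% signature$feature, , drop = FALSE]
  call_of <- stats::setNames(signature$call, signature$feature)
  sub <- split(g$feature, g$subsystem)
  rows <- lapply(names(sub), function(s) {
    calls <- call_of[sub[[s]]]
    data.frame(subsystem = s, n = length(calls),
               up = sum(calls == "up"), down = sum(calls == "down"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$da <- (out$up - out$down) / out$n
  out
}

#' Bootstrap (label-shuffle) significance of subsystem DA scores
#'
#' Recomputes the full dual-model pipeline under `B` random shuffles of
#' the group labels (ages and sexes stay attached to their samples), and
#' scores each subsystem's observed DA against its shuffle distribution:
#' `p = #(random DA >= observed)/B` for positive scores,
#' `#(random DA <= observed)/B` for negative scores, and 1 when the
#' observed DA is 0. Ties count as exceeding — the standard permutation
#' convention, which keeps the test valid when DA scores are coarsely
#' discrete (small subsystems put substantial probability on exact
#' ties). P-values are adjusted across subsystems by Benjamini-Hochberg.
#'
#' @inheritParams fit_model1
#' @param grouping feature -> subsystem map as in [da_score()].
#' @param B number of shuffles.
#' @param alpha call threshold passed to [call_signature()].
#' @param seed integer seed; fixed seed gives identical results.
#' @param smoothed use `(count + 1) / (B + 1)` instead of the raw
#'   fraction.
#' @return a `da_result` data.frame: `subsystem`, `n`, `up`, `down`,
#'   `da`, `p`, `fdr`.
#' @export
da_bootstrap <- function(mat, design, grouping, case, control, B = 1000,
                         alpha = 0.05, seed = 1, smoothed = FALSE) {
  if (B < 100) warning("B < 100 gives a coarse permutation p-value")
  d <- .design_subset(mat, design, c(case, control))
  Y <- t(mat[, d$sample, drop = FALSE])
  keep <- apply(Y, 2, stats::sd) > 0
  Y <- Y[, keep, drop = FALSE]
  male <- as.numeric(d$sex == "male")
  age <- d$age
  feats <- colnames(Y)
  g <- grouping[grouping$feature %in% feats, , drop = FALSE]
  sub_of <- split(g$feature, g$subsystem)
  subsystems <- names(sub_of)
  da_from_groups <- function(grp) {
    is_case <- grp == case
    is_ctrl <- grp == control
    X1 <- cbind(1, as.numeric(is_case), male)
    f1 <- .lm_beta_p(Y, X1, term = 2L)
    Yc <- Y[is_ctrl, , drop = FALSE]
    keep2 <- apply(Yc, 2, stats::sd) > 0
    X2 <- cbind(1, age[is_ctrl], male[is_ctrl])
    beta2 <- rep(0, ncol(Y)); p2 <- rep(1, ncol(Y))
    if (any(keep2)) {
      f2 <- .lm_beta_p(Yc[, keep2, drop = FALSE], X2, term = 2L)
      beta2[keep2] <- f2$beta
      p2[keep2] <- f2$p
    }
    calls <- .call_rule(f1$beta, f1$p, beta2, p2, alpha)
    names(calls) <- feats
    vapply(subsystems, function(s) {
      cl <- calls[sub_of[[s]]]
      (sum(cl == "up") - sum(cl == "down")) / length(cl)
    }, numeric(1))
  }
  obs <- da_from_groups(d$group)
  set.seed(seed)
  rand <- matrix(NA_real_, length(subsystems), B,
                 dimnames = list(subsystems, NULL))
  for (bb in seq_len(B)) {
    rand[, bb] <- da_from_groups(sample(d$group))
  }
  count <- vapply(seq_along(subsystems), function(i) {
    if (obs[i] > 0) sum(rand[i, ] >= obs[i])
    else if (obs[i] < 0) sum(rand[i, ] <= obs[i])
    else NA_integer_
  }, numeric(1))
  p <- if (smoothed) (count + 1) / (B + 1) else count / B
  p[is.na(count)] <- 1
  obs_counts <- da_score(
    call_signature(fit_model1(mat, design, case, control),
                   fit_model2(mat, design, control), alpha = alpha),
    grouping)
  out <- obs_counts[match(subsystems, obs_counts$subsystem), ,
                    drop = FALSE]
  out$p <- p
  out$fdr <- stats::p.adjust(p, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("da_result", "data.frame")
  out
}

#' Welch's t-test from summary statistics
#'
#' Unequal-variance two-sample t-test computed from group means, SDs and
#' sizes, as used for comparing published cohort attributes when only the
#' printed summaries are available.
#'
#' @param mean1,sd1,n1 first group summary (`sd1 > 0`, `n1 >= 2`).
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df` (Welch-Satterthwaite) and two-sided `p`.
#' @export
#' @examples
#' welch_t_from_summary(146.0, 20.1, 76, 137.9, 18.0, 41)$p  # ~0.03
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(sd1 > 0, sd2 > 0, n1 >= 2, n2 >= 2)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  tval <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Sum of the probabilities of all tables (with the observed margins) no
#' more probable than the observed one. A table with a zero margin is
#' uninformative and returns p = 1 with a warning.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return two-sided p-value.
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(58, 40, 18, 1), 2))  # ~0.003
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(identical(dim(table), c(2L, 2L)), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("2x2 table has a zero margin; p = 1")
    return(1)
  }
  stats::fisher.test(table)$p.value
}

#' Correlate two signatures or model fits
#'
#' Pearson correlation between the beta vectors of two fits over their
#' shared features — e.g. a case signature against the aging effect, or
#' signatures of two related groups.
#'
#' @param a,b `model_fit` or `signature_result` objects (for signatures,
#'   the model-1 beta is used).
#' @return list with `r`, `p`, `n` (shared features).
#' @export
compare_signatures <- function(a, b) {
  beta_of <- function(x) {
    if ("beta" %in% names(x)) stats::setNames(x$beta, x$feature)
    else stats::setNames(x$beta1, x$feature)
  }
  ba <- beta_of(a); bb <- beta_of(b)
  shared <- intersect(names(ba), names(bb))
  if (length(shared) < 3L) {
    stop("need >= 3 shared features, found ", length(shared))
  }
  ct <- stats::cor.test(ba[shared], bb[shared], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
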