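#' Deterministic toy core-metabolism fixture
#'
#' An 8-reaction glucose/oxygen network with the classic
#' fermentation-versus-respiration trade-off: glucose and oxygen exchanges
#' and transporters, a fermentation reaction (2 ATP per glucose, lactate
#' secreted), a respiration reaction (32 ATP per glucose, 6 O2), and an
#' ATP demand used as objective. With the default caps (glucose uptake 10,
#' O2 uptake 12 mmol/L/min) the analytic FBA optimum is
#' `32 * o2_cap/o2_per_glc + 2 * (glc_cap - o2_cap/o2_per_glc)` = 80:
#' respiration is oxygen-limited at 2 glucose, the remaining 8 ferment.
#'
#' The companion Kcat table and expression matrix give the fermentation
#' and respiration reactions binding kinetic caps (Vmax 9.0 and 0.9
#' mmol/L/min at the base expression), so per-sample flux predictions
#' respond to expression perturbations.
#'
#' @param seed seed for the per-sample expression noise.
#' @param glc_cap,o2_cap uptake caps (mmol/L/min).
#' @param ferm_atp,resp_atp ATP yields per glucose.
#' @param o2_per_glc O2 stoichiometry of respiration.
#' @param kcat_coverage which enzymatic reactions carry Kcat records.
#' @param n_samples columns of the expression matrix.
#' @param expr_sd log-normal spread of per-sample expression around the
#'   base profile (SD on the natural-log scale).
#' @return list with `model` (a `metabolic_model`), `kcats`
#'   (a `kcat_table`), `expression` (gene x sample FPKM matrix), `ratios`
#'   (a `protein_ratio_table`), and `manifest` (analytic expectations:
#'   `atp_optimum`, `lactate_if_no_respiration`, base Vmax values).
#' @export
make_toy_model <- function(seed = 1, glc_cap = 10, o2_cap = 12,
                           ferm_atp = 2, resp_atp = 32, o2_per_glc = 6,
                           kcat_coverage = c("FERM", "RESP"),
                           n_samples = 6, expr_sd = 0.1) {
  stopifnot(glc_cap >= 0, o2_cap >= 0, ferm_atp > 0, resp_atp > 0)
  mets <- data.frame(
    id = c("glc_e", "o2_e", "lac_e", "glc_c", "o2_c", "atp_c"),
    name = c("glucose (ext)", "oxygen (ext)", "lactate (ext)",
             "glucose", "oxygen", "ATP"),
    compartment = c("e", "e", "e", "c", "c", "c"),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_glc", "EX_o2", "EX_lac", "GLCt", "O2t", "FERM", "RESP",
           "ATPM"),
    lower_bound = c(-glc_cap, -o2_cap, 0, 0, 0, 0, 0, 0),
    upper_bound = c(0, 0, 1000, 1000, 1000, 1000, 1000, 1000),
    subsystem = c("Exchange", "Exchange", "Exchange", "Transport",
                  "Transport", "Glycolysis", "Oxidative phosphorylation",
                  "Energy demand"),
    ec = c("", "", "", "", "", "1.1.1.27", "1.3.5.1", ""),
    gpr = c("", "", "", "", "", "(g_ferm1 and g_ferm2) or g_ferm3",
            "g_resp", ""),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- list(
    c(glc_e = -1), c(o2_e = -1), c(lac_e = -1),
    c(glc_e = -1, glc_c = 1), c(o2_e = -1, o2_c = 1),
    c(glc_c = -1, lac_e = ferm_atp, atp_c = ferm_atp),
    c(glc_c = -1, o2_c = -o2_per_glc, atp_c = resp_atp),
    c(atp_c = -1))
  model <- metabolic_model(mets, rx, objective = c(ATPM = 1))

  kc <- data.frame(key = c("1.1.1.27", "1.3.5.1"), kcat = c(100, 50),
                   species = "Homo sapiens", provenance = "measured-human",
                   stringsAsFactors = FALSE)
  kc <- kc[c("FERM", "RESP") %in% kcat_coverage, , drop = FALSE]
  kcats <- kcat_table(kc)

  base <- c(g_ferm1 = 1, g_ferm2 = 2, g_ferm3 = 0.5, g_resp = 0.3)
  set.seed(seed)
  expr <- matrix(base, length(base), n_samples,
                 dimnames = list(names(base),
                                 sprintf("S%02d", seq_len(n_samples))))
  expr <- expr * exp(matrix(stats::rnorm(length(base) * n_samples,
                                         sd = expr_sd),
                            length(base), n_samples))
  ratios <- protein_ratio_table(
    stats::setNames(rep(1000, length(base)), names(base)))

  resp_glc <- min(glc_cap, o2_cap / o2_per_glc)
  manifest <- list(
    atp_optimum = resp_atp * resp_glc + ferm_atp * (glc_cap - resp_glc),
    lactate_if_no_respiration = ferm_atp * glc_cap,
    base_vmax = c(
      FERM = 100 * 60 * 1e-6 *
        (min(base[["g_ferm1"]], base[["g_ferm2"]]) + base[["g_ferm3"]]) *
        1000,
      RESP = 50 * 60 * 1e-6 * base[["g_resp"]] * 1000))
  list(model = model, kcats = kcats, expression = expr, ratios = ratios,
       manifest = manifest)
}

#' Parallel-path fixture for model reduction
#'
#' A linear chain from an uptake to a demand objective with two parallel
#' conversion routes: one catalyzed by an enzyme with a Kcat record, one
#' without. GIMME-style reduction should drop the uncovered route while
#' preserving the objective — unless `drop_covered = TRUE`, which deletes
#' the covered route so the uncovered one becomes the sole path and must
#' be retained.
#'
#' @param drop_covered delete the Kcat-covered branch.
#' @return list with `model` and `kcats`.
#' @export
make_reduction_fixture <- function(drop_covered = FALSE) {
  mets <- data.frame(
    id = c("A_e", "A_c", "B_c", "C_c"),
    name = c("A (ext)", "A", "B", "C"),
    compartment = c("e", "c", "c", "c"),
    stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_A", "At", "Rcov", "Runc", "Rout", "DM_C"),
    lower_bound = c(-10, 0, 0, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000, 1000, 1000),
    subsystem = c("Exchange", "Transport", "Conversion", "Conversion",
                  "Conversion", "Demand"),
    ec = c("", "", "1.1.1.1", "9.9.9.9", "2.2.2.2", ""),
    gpr = c("", "", "g_cov", "g_unc", "g_out", ""),
    stringsAsFactors = FALSE)
  rx$stoichiometry <- list(
    c(A_e = -1), c(A_e = -1, A_c = 1), c(A_c = -1, B_c = 1),
    c(A_c = -1, B_c = 1), c(B_c = -1, C_c = 1), c(C_c = -1))
  model <- metabolic_model(mets, rx, objective = c(DM_C = 1))
  if (drop_covered) {
    model <- subset_model(model, setdiff(model$reactions$id, "Rcov"))
  }
  kcats <- kcat_table(data.frame(
    key = c("1.1.1.1", "2.2.2.2"), kcat = c(10, 10),
    stringsAsFactors = FALSE))
  list(model = model, kcats = kcats)
}

#' One-dimensional flux polytope fixture
#'
#' A reversible chain `A_ex <-> A <-> B <-> B_ex` with every bound at
#' `c(-bound, bound)`. Steady state collapses it to a single free flux
#' uniform on `[-bound, bound]`, giving the sampler a closed-form target
#' distribution.
#'
#' @param bound absolute flux bound.
#' @return a `metabolic_model` with reactions `EX_A`, `AB`, `EX_B`.
#' @export
make_chain_model <- function(bound = 1) {
  mets <- data.frame(id = c("A", "B"), name = c("A", "B"),
                     compartment = "c", stringsAsFactors = FALSE)
  rx <- data.frame(
    id = c("EX_A", "AB", "EX_B"),
    lower_bound = -bound, upper_bound = bound,
    stringsAsFactors = FALSE)
  rx$stoichiometry <- list(c(A = -1), c(A = -1, B = 1), c(B = -1))
  metabolic_model(mets, rx)
}

#' Synthetic cohort generator with planted signal
#'
#' Emulates the statistical structure the signature engine assumes: a
#' feature x sample abundance matrix with a case group and a control
#' group, linear group/age/sex effects and log-normal noise. All features
#' of the planted subsystem are shifted multiplicatively in the case
#' group; a configurable fraction of features gets an age slope within
#' the control group; a sex offset and Gaussian log-scale noise apply to
#' every feature. Ground-truth labels are returned so recovery can be
#' scored without re-deriving them.
#'
#' @param seed integer seed.
#' @param n_case,n_control group sizes (>= 3).
#' @param case_group,control_group group labels in the design.
#' @param age_range_case,age_range_control sampled uniformly (years).
#' @param sex_ratio probability of `male`.
#' @param n_features,n_subsystems features are split evenly over
#'   subsystems `SS01..`.
#' @param planted_subsystem subsystem receiving the case shift.
#' @param effect multiplicative case-group shift (1 = null cohort).
#' @param aging_frac fraction of non-planted features with an age slope in
#'   controls.
#' @param aging_slope log2 units per year of age (in controls).
#' @param sex_offset log2 offset for male samples.
#' @param noise_sd log2-scale noise SD.
#' @return list with `matrix` (feature x sample, natural scale), `design`
#'   (data.frame sample/group/age/sex), `grouping` (data.frame
#'   feature/subsystem), and `truth` (planted and aging feature ids).
#' @export
make_synthetic_cohort <- function(seed = 1, n_case = 40, n_control = 40,
                                  case_group = "CEN",
                                  control_group = "F1SP",
                                  age_range_case = c(98, 108),
                                  age_range_control = c(45, 75),
                                  sex_ratio = 0.5, n_features = 200,
                                  n_subsystems = 10,
                                  planted_subsystem = "SS01",
                                  effect = 1.5, aging_frac = 0.1,
                                  aging_slope = 0.02, sex_offset = 0.1,
                                  noise_sd = 0.3) {
  stopifnot(n_case >= 3, n_control >= 3, effect > 0)
  set.seed(seed)
  n <- n_case + n_control
  design <- data.frame(
    sample = sprintf("P%03d", seq_len(n)),
    group = c(rep(case_group, n_case), rep(control_group, n_control)),
    age = c(round(stats::runif(n_case, age_range_case[1],
                               age_range_case[2])),
            round(stats::runif(n_control, age_range_control[1],
                               age_range_control[2]))),
    sex = ifelse(stats::runif(n) < sex_ratio, "male", "female"),
    stringsAsFactors = FALSE)
  feats <- sprintf("F%03d", seq_len(n_features))
  subsys <- sprintf("SS%02d", rep(seq_len(n_subsystems),
                                  length.out = n_features))
  subsys <- sort(subsys)
  grouping <- data.frame(feature = feats, subsystem = subsys,
                         stringsAsFactors = FALSE)
  planted <- feats[subsys == planted_subsystem]
  candidates <- setdiff(feats, planted)
  aging <- sample(candidates, round(aging_frac * length(candidates)))
  base_log2 <- stats::runif(n_features, 0, 3)
  is_case <- design$group == case_group
  is_ctrl <- design$group == control_group
  ctrl_age_center <- mean(design$age[is_ctrl])
  L <- matrix(base_log2, n_features, n,
              dimnames = list(feats, design$sample))
  L[planted, is_case] <- L[planted, is_case] + log2(effect)
  age_dev <- design$age - ctrl_age_center
  L[aging, is_ctrl] <- L[aging, is_ctrl] +
    aging_slope * matrix(age_dev[is_ctrl], length(aging), sum(is_ctrl),
                         byrow = TRUE)
  L[, design$sex == "male"] <- L[, design$sex == "male"] + sex_offset
  L <- L + matrix(stats::rnorm(n_features * n, sd = noise_sd),
                  n_features, n)
  list(matrix = 2^L, design = design, grouping = grouping,
       truth = list(planted_features = planted,
                    planted_subsystem = planted_subsystem,
                    aging_features = aging))
}
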