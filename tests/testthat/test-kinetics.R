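test_that("alpha/gamma ratios are per-gene medians with a global fallback", {
  mrna <- rbind(gA = c(2, 3, 4), gB = c(1, 1, 1), gC = c(0, 0, 0),
                gD = c(1, 2, 0), gE = c(10, 10, 10))
  prot <- rbind(gA = c(4, 6, 8), gB = c(1, 2, 9), gC = c(5, 5, 5),
                gD = c(3, 2, 7), gE = c(10, 20, 30))
  colnames(mrna) <- colnames(prot) <- paste0("t", 1:3)
  rt <- estimate_alpha_gamma(mrna, prot)
  expect_equal(rt$ratio[rt$gene == "gA"], 2.0)   # all tissue ratios 2
  expect_equal(rt$ratio[rt$gene == "gB"], 2.0)   # median of {1, 2, 9}
  # gC has no usable tissue: flagged, gets the global fallback
  expect_true(rt$fallback[rt$gene == "gC"])
  # per-gene medians: gA 2, gB 2, gD median(3, 1) = 2, gE 2 -> global 2
  expect_equal(attr(rt, "global_ratio"), 2.0)
  expect_equal(rt$ratio[rt$gene == "gC"], 2.0)
  # zero-mRNA tissue skipped for gD: ratios {3, 1}, median 2
  expect_equal(rt$ratio[rt$gene == "gD"], 2.0)
  expect_error(estimate_alpha_gamma(mrna * 0, prot), "usable")
})

test_that("enzyme abundance is ratio x transcript with fallback genes", {
  rt <- protein_ratio_table(c(g1 = 2, g2 = 4), global_ratio = 10)
  e <- estimate_enzyme_abundance(c(g1 = 3, g2 = 0, g9 = 5), rt)
  expect_equal(unname(e), c(2 * 3, 0, 10 * 5))
})

test_that("effective enzyme follows OR = sum, AND = min", {
  ab <- c(g1 = 2, g2 = 5, g3 = 1)
  expect_equal(effective_enzyme("(g1 and g2) or g3", ab), 3)
  expect_equal(effective_enzyme("g1 or g2", ab), 7)
  expect_equal(effective_enzyme("g1 and g2", ab), 2)
  expect_equal(effective_enzyme("", ab), Inf)
  expect_equal(effective_enzyme("g1 and g_missing", ab), 0)
})

test_that("effective enzyme is monotone and bounded by its children", {
  set.seed(3)
  rule <- parse_gpr("((g1 and g2) or (g3 and g4 and g5)) or g6")
  for (i in 1:25) {
    ab <- setNames(runif(6, 0, 10), paste0("g", 1:6))
    base <- effective_enzyme(rule, ab)
    # raising any one gene never lowers the result
    g <- sample(names(ab), 1)
    ab2 <- ab; ab2[g] <- ab2[g] + runif(1, 0, 5)
    expect_gte(effective_enzyme(rule, ab2), base)
    # OR >= each child; AND <= each child
    or_children <- c(min(ab["g1"], ab["g2"]),
                     min(ab["g3"], ab["g4"], ab["g5"]), ab[["g6"]])
    expect_true(all(base >= or_children - 1e-12))
    expect_lte(effective_enzyme("g1 and g2", ab), min(ab["g1"], ab["g2"]))
  }
})

test_that("kcat lookup prefers reaction ids, pools ECs, takes medians", {
  kt <- kcat_table(data.frame(
    key = c("RXN1", "RXN1", "1.1.1.1", "1.1.1.1", "2.2.2.2"),
    kcat = c(10, 30, 5, 7, 100)))
  expect_equal(kcat_lookup(kt, "RXN1", "1.1.1.1"), 20)  # reaction first
  expect_equal(kcat_lookup(kt, "RXNX", "1.1.1.1"), 6)
  expect_equal(kcat_lookup(kt, "RXNX", "1.1.1.1; 2.2.2.2"),
               median(c(5, 7, 100)))
  expect_true(is.na(kcat_lookup(kt, "RXNX", "9.9.9.9")))
  expect_error(kcat_table(data.frame(key = "a", kcat = -1)), "> 0")
})

test_that("reaction Vmax applies the unit pipeline and the whitelist", {
  # single-reaction model: Kcat 100/s, E 500 nmol/L -> 3.0 mmol/L/min
  mets <- data.frame(id = c("a", "b"), compartment = "c")
  rx <- data.frame(id = c("R1", "ATPS4mi", "R3"),
                   lower_bound = 0, upper_bound = 1000,
                   ec = c("1.1.1.1", "3.6.3.14", ""),
                   gpr = c("gx", "gx", "gy"))
  rx$stoichiometry <- list(c(a = -1, b = 1), c(a = -1, b = 1),
                           c(b = -1, a = 1))
  m <- metabolic_model(mets, rx)
  kt <- kcat_table(data.frame(key = c("1.1.1.1", "3.6.3.14"),
                              kcat = c(100, 100)))
  ctx <- suppressMessages(reaction_vmax(m, c(gx = 500, gy = 500), kt))
  expect_equal(unname(ctx$vmax["R1"]), 3.0)
  # whitelisted oxidative-phosphorylation reaction stays unlimited
  expect_equal(unname(ctx$vmax["ATPS4mi"]), Inf)
  # no Kcat record -> unlimited
  expect_equal(unname(ctx$vmax["R3"]), Inf)
})

test_that("Vmax scales linearly in enzyme abundance", {
  toy <- make_toy_model()
  ab <- estimate_enzyme_abundance(toy$expression[, 1], toy$ratios)
  c1 <- suppressMessages(reaction_vmax(toy$model, ab, toy$kcats))
  c2 <- suppressMessages(reaction_vmax(toy$model, ab * 2, toy$kcats))
  finite <- is.finite(c1$vmax)
  expect_equal(c2$vmax[finite], 2 * c1$vmax[finite])
  expect_equal(c2$vmax[!finite], c1$vmax[!finite])
})

test_that("kinetic bounds cap reactions symmetrically and never widen", {
  toy <- make_toy_model()
  m <- toy$model
  # make FERM reversible to exercise the symmetric cap
  m$reactions$lower_bound[m$reactions$id == "FERM"] <- -1000
  m$reactions$reversible <- m$reactions$lower_bound < 0
  ctx <- suppressMessages(reaction_vmax(
    m, c(g_ferm1 = 10000, g_ferm2 = 40000, g_ferm3 = 0, g_resp = 100),
    toy$kcats))
  # FERM: kcat 100 * 60 * min(1e4, 4e4) * 1e-6 = 60
  expect_equal(unname(ctx$vmax["FERM"]), 60)
  m2 <- apply_kinetic_bounds(m, ctx)
  i <- match("FERM", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], -60)
  expect_equal(m2$reactions$upper_bound[i], 60)
  # interior bounds never widen
  interior <- !kinflux:::.is_boundary(m)
  expect_true(all(m2$reactions$lower_bound[interior] >=
                    m$reactions$lower_bound[interior]))
  expect_true(all(m2$reactions$upper_bound[interior] <=
                    m$reactions$upper_bound[interior]))
})

test_that("uptake configuration sets exchange bounds by category", {
  toy <- make_toy_model()
  ab <- estimate_enzyme_abundance(toy$expression[, 1], toy$ratios)
  ctx <- suppressMessages(reaction_vmax(toy$model, ab, toy$kcats))
  cfg <- data.frame(
    exchange_id = c("EX_glc", "EX_o2", "EX_lac", "EX_ghost"),
    category = c("nutrient", "iron_oxygen", "essential_amino_acid",
                 "nutrient"),
    uptake_bound = c(10, NA, NA, 5),
    secretion_bound = c(0, NA, NA, NA))
  expect_warning(m2 <- apply_kinetic_bounds(toy$model, ctx, cfg),
                 "EX_ghost")
  rx <- m2$reactions
  expect_equal(rx$lower_bound[rx$id == "EX_glc"], -10)
  expect_equal(rx$lower_bound[rx$id == "EX_o2"], -1000)   # unlimited
  expect_equal(rx$lower_bound[rx$id == "EX_lac"], -0.01)  # small default
})
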