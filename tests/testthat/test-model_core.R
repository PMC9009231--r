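toy <- make_toy_model()

test_that("the toy core fixture builds a validated 8-reaction model", {
  m <- toy$model
  expect_s3_class(m, "metabolic_model")
  expect_equal(nrow(m$reactions), 8)
  expect_equal(names(m$objective), "ATPM")
  expect_silent(validate_model(m))
})

test_that("structural validation catches broken models", {
  m <- toy$model
  bad <- m
  bad$reactions$stoichiometry[[1]] <- c(ghost_met = -1)
  expect_error(validate_model(bad), "ghost_met")
  bad2 <- m
  bad2$reactions$lower_bound[4] <- 5
  bad2$reactions$upper_bound[4] <- 2
  expect_error(validate_model(bad2), "lower_bound > upper_bound")
  bad3 <- m
  bad3$genes <- setdiff(bad3$genes, "g_resp")
  expect_error(validate_model(bad3), "g_resp")
})

test_that("JSON round trip preserves structure, bounds and GPR trees", {
  path <- withr::local_tempfile(fileext = ".json")
  write_model(toy$model, path)
  m2 <- load_model(path)
  expect_equal(nrow(m2$reactions), nrow(toy$model$reactions))
  expect_equal(m2$reactions$lower_bound, toy$model$reactions$lower_bound,
               tolerance = 1e-12)
  expect_equal(m2$reactions$upper_bound, toy$model$reactions$upper_bound,
               tolerance = 1e-12)
  expect_equal(m2$objective, toy$model$objective)
  expect_equal(m2$reactions$subsystem, toy$model$reactions$subsystem)
  expect_equal(m2$reactions$ec, toy$model$reactions$ec)
  for (j in seq_len(nrow(m2$reactions))) {
    expect_true(gpr_equal(m2$reactions$gpr_rule[[j]],
                          toy$model$reactions$gpr_rule[[j]]))
    expect_equal(sort(names(m2$reactions$stoichiometry[[j]])),
                 sort(names(toy$model$reactions$stoichiometry[[j]])))
  }
  # write -> load -> write is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("SBML round trip preserves structure, bounds and GPR trees", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(toy$model, path)
  m2 <- load_model(path)
  expect_equal(nrow(m2$reactions), nrow(toy$model$reactions))
  expect_equal(m2$reactions$id, toy$model$reactions$id)
  expect_equal(m2$reactions$lower_bound, toy$model$reactions$lower_bound,
               tolerance = 1e-12)
  expect_equal(m2$reactions$upper_bound, toy$model$reactions$upper_bound,
               tolerance = 1e-12)
  expect_equal(m2$reactions$subsystem, toy$model$reactions$subsystem)
  expect_equal(m2$reactions$ec, toy$model$reactions$ec)
  expect_equal(sort(names(m2$objective)), sort(names(toy$model$objective)))
  for (j in seq_len(nrow(m2$reactions))) {
    expect_true(gpr_equal(m2$reactions$gpr_rule[[j]],
                          toy$model$reactions$gpr_rule[[j]]))
    st1 <- m2$reactions$stoichiometry[[j]]
    st0 <- toy$model$reactions$stoichiometry[[j]]
    expect_equal(st1[sort(names(st1))], st0[sort(names(st0))])
  }
})

test_that("SBML reactions without fbc bounds fall back to defaults with a warning", {
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(toy$model, path)
  txt <- readLines(path)
  txt <- gsub('fbc:lowerFluxBound="[^"]*" ?', "", txt)
  txt <- gsub('fbc:upperFluxBound="[^"]*" ?', "", txt)
  writeLines(txt, path)
  expect_warning(m2 <- load_model(path), "defaults")
  rev <- m2$reactions$reversible
  expect_true(all(m2$reactions$upper_bound == 1000))
  expect_true(all(m2$reactions$lower_bound[rev] == -1000))
  expect_true(all(m2$reactions$lower_bound[!rev] == 0))
})

test_that("malformed model files raise parse errors naming the problem", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines("{ not valid json", p)
  expect_error(load_model(p), "malformed")
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(metabolites = list()), p2, auto_unbox = TRUE)
  expect_error(load_model(p2), "reactions")
  p3 <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model></model>", p3)
  expect_error(load_model(p3), "malformed")
})

test_that("reaction classification matches the component rules and is a partition", {
  comp <- classify_reactions(toy$model)
  expect_equal(unname(comp["EX_glc"]), "uptake")       # lb < 0 exchange
  expect_equal(unname(comp["EX_lac"]), "secretion_demand")
  expect_equal(unname(comp["ATPM"]), "secretion_demand")  # demand atp -> 0
  expect_equal(unname(comp["GLCt"]), "transport")      # e -> c, no EC
  expect_equal(unname(comp["FERM"]), "enzymatic")
  # exhaustive and mutually exclusive: one label per reaction
  expect_equal(length(comp), nrow(toy$model$reactions))
  expect_true(all(comp %in% c("uptake", "transport", "enzymatic",
                              "secretion_demand")))
})

test_that("curation directives are applied and never widen bounds", {
  m <- toy$model
  m$reactions$lower_bound[m$reactions$id == "GLCt"] <- -10
  m$reactions$reversible <- m$reactions$lower_bound < 0
  cur <- data.frame(reaction_id = "GLCt", directive = "make-irreversible")
  m2 <- apply_curation(m, cur)
  i <- match("GLCt", m2$reactions$id)
  expect_equal(m2$reactions$lower_bound[i], 0)
  expect_equal(m2$reactions$upper_bound[i], 1000)
  expect_false(m2$reactions$reversible[i])
  # bounds never widen
  expect_true(all(m2$reactions$lower_bound >= m$reactions$lower_bound))
  expect_true(all(m2$reactions$upper_bound <= m$reactions$upper_bound))
  # identity and error cases
  expect_identical(apply_curation(m, data.frame()), m)
  expect_error(
    apply_curation(m, data.frame(reaction_id = "RXN_X",
                                 directive = "make-irreversible")),
    "RXN_X")
})

test_that("add_reaction inserts a reaction and its new metabolites", {
  m2 <- add_reaction(toy$model, "LDH_alt", c(glc_c = -1, atp_c = 1),
                     gpr = "g_new", ec = "1.1.1.99")
  expect_true("LDH_alt" %in% m2$reactions$id)
  expect_true("g_new" %in% m2$genes)
  expect_error(add_reaction(m2, "LDH_alt", c(glc_c = -1)), "already")
})
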