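# JSON model dialect: a close cousin of the de facto community JSON layout
# (objects for metabolites/reactions/genes; stoichiometry as an object of
# metabolite id -> coefficient; objective weights on the reactions).

.read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON model '", path, "': ",
                             conditionMessage(e)))
  for (el in c("metabolites", "reactions")) {
    if (is.null(doc[[el]])) stop("JSON model lacks element '", el, "'")
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (is.null(m$name)) m$id else m$name,
               compartment = if (is.null(m$compartment)) "c"
                             else m$compartment,
               stringsAsFactors = FALSE)
  }))
  rxl <- doc$reactions
  rx <- do.call(rbind, lapply(rxl, function(r) {
    if (is.null(r$id)) stop("JSON model: reaction without an 'id'")
    data.frame(id = r$id,
               name = if (is.null(r$name)) r$id else r$name,
               lower_bound = if (is.null(r$lower_bound)) NA_real_
                             else r$lower_bound,
               upper_bound = if (is.null(r$upper_bound)) NA_real_
                             else r$upper_bound,
               reversible = if (is.null(r$lower_bound)) NA
                            else r$lower_bound < 0,
               subsystem = if (is.null(r$subsystem)) "" else r$subsystem,
               ec = if (is.null(r$ec_number)) "" else r$ec_number,
               gpr = if (is.null(r$gene_reaction_rule)) ""
                     else r$gene_reaction_rule,
               stringsAsFactors = FALSE)
  }))
  rx$stoichiometry <- lapply(rxl, function(r) {
    s <- unlist(r$metabolites)
    if (is.null(s)) stop("JSON model: reaction '", r$id,
                         "' has no metabolites")
    s
  })
  obj <- numeric()
  for (r in rxl) {
    w <- r$objective_coefficient
    if (!is.null(w) && w != 0) obj[r$id] <- w
  }
  genes <- vapply(doc$genes, function(g) g$id, character(1))
  metabolic_model(mets, rx, genes = genes, objective = obj)
}

.write_model_json <- function(model, path) {
  rx <- model$reactions
  reactions <- lapply(seq_len(nrow(rx)), function(j) {
    out <- list(
      id = rx$id[j], name = rx$name[j],
      metabolites = as.list(rx$stoichiometry[[j]]),
      lower_bound = rx$lower_bound[j], upper_bound = rx$upper_bound[j],
      subsystem = rx$subsystem[j], ec_number = rx$ec[j],
      gene_reaction_rule = rx$gpr[j])
    w <- model$objective[rx$id[j]]
    if (!is.na(w)) out$objective_coefficient <- unname(w)
    out
  })
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    list(id = model$metabolites$id[i], name = model$metabolites$name[i],
         compartment = model$metabolites$compartment[i])
  })
  genes <- lapply(model$genes, function(g) list(id = g))
  jsonlite::write_json(
    list(metabolites = mets, reactions = reactions, genes = genes),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
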