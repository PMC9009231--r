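#' Construct a genome-scale metabolic model
#'
#' The container behind all flux computation: a stoichiometric network with
#' per-reaction bounds (mmol/L/min), subsystem labels, EC numbers and
#' gene-protein-reaction (GPR) rules. Exchange reactions follow the
#' dominant community convention `metabolite -> (nothing)`, with uptake
#' encoded as negative flux.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `ec`, `gpr` (rule text) and a list-column
#'   `stoichiometry` of named numeric vectors (metabolite id ->
#'   coefficient). Missing optional columns are filled with defaults;
#'   missing bounds default to (-1000, 1000) for `reversible = TRUE` and
#'   (0, 1000) otherwise.
#' @param genes character vector of gene ids; genes referenced by GPR rules
#'   are always included.
#' @param objective named numeric vector (reaction id -> weight).
#'
#' @return object of class `metabolic_model` with elements `metabolites`,
#'   `reactions` (including parsed `gpr_rule` list-column), `genes`,
#'   `objective`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = character(),
                            objective = numeric()) {
  metabolites <- as.data.frame(metabolites)
  reactions <- as.data.frame(reactions)
  for (col in c("id")) {
    if (!col %in% names(metabolites)) stop("metabolites need an 'id' column")
    if (!col %in% names(reactions)) stop("reactions need an 'id' column")
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!"compartment" %in% names(metabolites)) metabolites$compartment <- "c"
  if (!"stoichiometry" %in% names(reactions)) {
    stop("reactions need a 'stoichiometry' list-column")
  }
  if (!"name" %in% names(reactions)) reactions$name <- reactions$id
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (!"ec" %in% names(reactions)) reactions$ec <- ""
  if (!"gpr" %in% names(reactions)) reactions$gpr <- ""
  reactions$ec[is.na(reactions$ec)] <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  reactions$subsystem[is.na(reactions$subsystem)] <- ""
  if (!"reversible" %in% names(reactions)) reactions$reversible <- NA
  if (!"lower_bound" %in% names(reactions)) reactions$lower_bound <- NA_real_
  if (!"upper_bound" %in% names(reactions)) reactions$upper_bound <- NA_real_
  miss <- is.na(reactions$lower_bound) | is.na(reactions$upper_bound)
  if (any(miss)) {
    rev <- ifelse(is.na(reactions$reversible), TRUE, reactions$reversible)
    reactions$lower_bound[miss] <- ifelse(rev[miss], -1000, 0)
    reactions$upper_bound[miss] <- 1000
  }
  reactions$reversible <- reactions$lower_bound < 0
  reactions$gpr_rule <- lapply(reactions$gpr, parse_gpr)
  gpr_gene_ids <- unique(unlist(lapply(reactions$gpr_rule, gpr_genes)))
  genes <- sort(unique(c(as.character(genes), gpr_gene_ids)))
  model <- structure(
    list(metabolites = metabolites, reactions = reactions,
         genes = genes, objective = objective),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks that every metabolite referenced by a stoichiometry exists, that
#' `lower_bound <= upper_bound` everywhere, that the reversible flag agrees
#' with `lower_bound < 0`, that every GPR gene appears in the gene list,
#' and that objective reactions exist.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; errors name the offending elements.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rx <- model$reactions
  if (anyDuplicated(rx$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rx$id[duplicated(rx$id)]), collapse = ", "))
  }
  if (anyDuplicated(model$metabolites$id)) {
    stop("duplicate metabolite ids")
  }
  refmet <- unique(unlist(lapply(rx$stoichiometry, names)))
  dangling <- setdiff(refmet, model$metabolites$id)
  if (length(dangling)) {
    stop("stoichiometry references unknown metabolite(s): ",
         paste(dangling, collapse = ", "))
  }
  bad <- rx$lower_bound > rx$upper_bound
  if (any(bad)) {
    stop("lower_bound > upper_bound for reaction(s): ",
         paste(rx$id[bad], collapse = ", "))
  }
  incons <- rx$reversible != (rx$lower_bound < 0)
  if (any(incons)) {
    stop("reversible flag inconsistent with bounds for: ",
         paste(rx$id[incons], collapse = ", "))
  }
  gg <- unique(unlist(lapply(rx$gpr_rule, gpr_genes)))
  missg <- setdiff(gg, model$genes)
  if (length(missg)) {
    stop("GPR references gene(s) absent from gene list: ",
         paste(missg, collapse = ", "))
  }
  if (length(model$objective)) {
    misso <- setdiff(names(model$objective), rx$id)
    if (length(misso)) {
      stop("objective references unknown reaction(s): ",
           paste(misso, collapse = ", "))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", nrow(x$metabolites), " metabolites, ",
      nrow(x$reactions), " reactions, ", length(x$genes), " genes\n",
      sep = "")
  if (length(x$objective)) {
    cat("objective:", paste(names(x$objective), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stoichiometric matrix of a model
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions.
#' @export
stoich_matrix <- function(model) {
  met <- model$metabolites$id
  rxn <- model$reactions$id
  S <- matrix(0, length(met), length(rxn), dimnames = list(met, rxn))
  for (j in seq_along(rxn)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

# boundary (exchange/demand/sink) reactions touch exactly one metabolite
.is_boundary <- function(model) {
  vapply(model$reactions$stoichiometry, function(s) length(s) == 1L,
         logical(1))
}

#' Classify reactions into functional components
#'
#' Partitions the reaction set into the four components of a genome-scale
#' network: `uptake` (boundary reactions allowed to run negative, i.e.
#' import), `secretion_demand` (boundary reactions restricted to
#' nonnegative flux), `transport` (non-boundary reactions that move species
#' between compartments without an EC number), and `enzymatic` (the rest).
#' The classification is total: every reaction gets exactly one label.
#'
#' @param model a validated `metabolic_model`.
#' @return named character vector, reaction id -> component.
#' @export
classify_reactions <- function(model) {
  validate_model(model)
  bnd <- .is_boundary(model)
  comp_of <- stats::setNames(model$metabolites$compartment,
                             model$metabolites$id)
  out <- character(nrow(model$reactions))
  for (j in seq_len(nrow(model$reactions))) {
    if (bnd[j]) {
      out[j] <- if (model$reactions$lower_bound[j] < 0) "uptake"
                else "secretion_demand"
    } else {
      comps <- unique(comp_of[names(model$reactions$stoichiometry[[j]])])
      no_ec <- !nzchar(model$reactions$ec[j])
      out[j] <- if (length(comps) > 1L && no_ec) "transport" else "enzymatic"
    }
  }
  stats::setNames(out, model$reactions$id)
}

#' Apply a curation list to a model
#'
#' Curation directives encode manual fixes to a generic network, such as
#' closing the thermodynamically impossible direction of a reversible
#' reaction. Supported directives: `make_irreversible` (lower bound raised
#' to at least 0, reversible flag cleared), `set_lower_bound` and
#' `set_upper_bound` (with `value`). Bounds are never widened by
#' `make_irreversible`.
#'
#' @param model a `metabolic_model`.
#' @param curation data.frame with columns `reaction_id`, `directive` and
#'   optionally `value`. Hyphenated directive spellings are accepted.
#' @return a new, revalidated `metabolic_model`.
#' @export
apply_curation <- function(model, curation) {
  curation <- as.data.frame(curation)
  if (nrow(curation) == 0L) return(model)
  stopifnot(all(c("reaction_id", "directive") %in% names(curation)))
  unknown <- setdiff(curation$reaction_id, model$reactions$id)
  if (length(unknown)) {
    stop("curation targets unknown reaction(s): ",
         paste(unknown, collapse = ", "))
  }
  rx <- model$reactions
  for (k in seq_len(nrow(curation))) {
    i <- match(curation$reaction_id[k], rx$id)
    d <- gsub("-", "_", tolower(curation$directive[k]))
    if (d == "make_irreversible") {
      rx$lower_bound[i] <- max(rx$lower_bound[i], 0)
    } else if (d == "set_lower_bound") {
      rx$lower_bound[i] <- as.numeric(curation$value[k])
    } else if (d == "set_upper_bound") {
      rx$upper_bound[i] <- as.numeric(curation$value[k])
    } else {
      stop("unknown curation directive: ", curation$directive[k])
    }
  }
  rx$reversible <- rx$lower_bound < 0
  model$reactions <- rx
  validate_model(model)
  model
}

#' Read a curation list from TSV
#' @param path TSV with columns `reaction_id`, `directive`, `value`.
#' @return data.frame usable with [apply_curation()].
#' @export
read_curation <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Keep only the given reactions (and the metabolites/genes they use)
#' @param model a `metabolic_model`.
#' @param keep_ids reaction ids to retain.
#' @return a new `metabolic_model`; objective entries outside `keep_ids`
#'   are dropped.
#' @export
subset_model <- function(model, keep_ids) {
  keep <- model$reactions$id %in% keep_ids
  rx <- model$reactions[keep, , drop = FALSE]
  rownames(rx) <- NULL
  used_met <- unique(unlist(lapply(rx$stoichiometry, names)))
  mets <- model$metabolites[model$metabolites$id %in% used_met, ,
                            drop = FALSE]
  rownames(mets) <- NULL
  used_genes <- unique(unlist(lapply(rx$gpr_rule, gpr_genes)))
  obj <- model$objective[names(model$objective) %in% rx$id]
  out <- model
  out$reactions <- rx
  out$metabolites <- mets
  out$genes <- sort(used_genes)
  out$objective <- obj
  validate_model(out)
  out
}

#' Add a reaction to a model
#'
#' Used, for example, to knock in a reaction before a [perturb_context()]
#' screen. New metabolites are created in the stated compartment.
#'
#' @param model a `metabolic_model`.
#' @param id reaction id (must be new).
#' @param stoichiometry named numeric vector, metabolite id -> coefficient.
#' @param lower_bound,upper_bound flux bounds (mmol/L/min).
#' @param subsystem,ec,gpr optional annotation.
#' @param compartment compartment assigned to newly created metabolites.
#' @return a new `metabolic_model`.
#' @export
add_reaction <- function(model, id, stoichiometry, lower_bound = 0,
                         upper_bound = 1000, subsystem = "", ec = "",
                         gpr = "", compartment = "c") {
  if (id %in% model$reactions$id) stop("reaction already present: ", id)
  newmet <- setdiff(names(stoichiometry), model$metabolites$id)
  if (length(newmet)) {
    model$metabolites <- rbind(
      model$metabolites,
      data.frame(id = newmet, name = newmet, compartment = compartment,
                 stringsAsFactors = FALSE))
  }
  row <- data.frame(id = id, name = id, lower_bound = lower_bound,
                    upper_bound = upper_bound,
                    reversible = lower_bound < 0, subsystem = subsystem,
                    ec = ec, gpr = gpr, stringsAsFactors = FALSE)
  row$stoichiometry <- list(stoichiometry)
  row$gpr_rule <- list(parse_gpr(gpr))
  model$reactions <- rbind(model$reactions[names(row)], row)
  model$genes <- sort(unique(c(model$genes, gpr_genes(row$gpr_rule[[1]]))))
  validate_model(model)
  model
}

#' Load a metabolic model from file
#'
#' Dispatches on extension: `.json` for the package's JSON dialect (see
#' [write_model()]), `.xml`/`.sbml` for SBML Level 3 with the `fbc`
#' package (bounds, objectives, gene products). SBML reactions lacking fbc
#' bound annotations default to (-1000, 1000) when marked reversible and
#' (0, 1000) otherwise, with a warning.
#'
#' @param path model file.
#' @param flux_scale optional multiplicative factor applied to all bounds
#'   at load, for model files whose bounds are not in mmol/L/min.
#' @return a validated `metabolic_model`.
#' @export
load_model <- function(path, flux_scale = 1) {
  ext <- tolower(tools::file_ext(path))
  model <- switch(ext,
    json = .read_model_json(path),
    xml = .read_model_sbml(path),
    sbml = .read_model_sbml(path),
    stop("unsupported model format: .", ext, " (use .json, .xml or .sbml)"))
  if (flux_scale != 1) {
    model$reactions$lower_bound <- model$reactions$lower_bound * flux_scale
    model$reactions$upper_bound <- model$reactions$upper_bound * flux_scale
  }
  validate_model(model)
  model
}

#' Write a metabolic model to file
#'
#' Same dialects as [load_model()]. A load/write/load round trip preserves
#' reaction counts, bounds, annotations and GPR tree structure.
#'
#' @param model a `metabolic_model`.
#' @param path output file (`.json`, `.xml` or `.sbml`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  validate_model(model)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = .write_model_json(model, path),
    xml = .write_model_sbml(model, path),
    sbml = .write_model_sbml(model, path),
    stop("unsupported model format: .", ext))
  invisible(path)
}
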