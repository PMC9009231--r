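# SBML Level 3 I/O with the fbc package (flux bounds, objectives, gene
# products). Identifiers follow the community convention of R_/M_/G_
# prefixes inside the file; they are stripped on read. Subsystem and EC
# annotations travel in the reaction notes body ("SUBSYSTEM: ...",
# "EC Number: ...").

.SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
.SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"
.XHTML_NS <- "http://www.w3.org/1999/xhtml"

.sbml_id <- function(prefix, id) paste0(prefix, gsub("[^A-Za-z0-9_]", "_", id))

.strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

# attribute lookup tolerant of namespace prefixes
.attr_any <- function(node, localname) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", localname, "$"), names(at))
  if (length(hit)) unname(at[hit[1]]) else NA_character_
}

.write_model_sbml <- function(model, path) {
  rx <- model$reactions
  doc <- xml2::xml_new_root(
    "sbml", xmlns = .SBML_CORE_NS, "xmlns:fbc" = .SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false")
  mnode <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "false")
  # compartments
  lc <- xml2::xml_add_child(mnode, "listOfCompartments")
  for (cp in unique(model$metabolites$compartment)) {
    xml2::xml_add_child(lc, "compartment", id = .sbml_id("", cp),
                        constant = "true")
  }
  # species
  ls <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    xml2::xml_add_child(
      ls, "species",
      id = .sbml_id("M_", model$metabolites$id[i]),
      name = model$metabolites$name[i],
      compartment = .sbml_id("", model$metabolites$compartment[i]),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false")
  }
  # flux-bound parameters, one per distinct value
  vals <- sort(unique(c(rx$lower_bound, rx$upper_bound)))
  key_of <- function(v) sprintf("%.17g", v)
  pid <- stats::setNames(sprintf("fb_%d", seq_along(vals)),
                         vapply(vals, key_of, character(1)))
  lp <- xml2::xml_add_child(mnode, "listOfParameters")
  for (k in seq_along(vals)) {
    xml2::xml_add_child(lp, "parameter", id = pid[[k]],
                        value = sprintf("%.17g", vals[k]),
                        constant = "true")
  }
  # gene products
  lg <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
  for (g in model$genes) {
    xml2::xml_add_child(lg, "fbc:geneProduct",
                        "fbc:id" = .sbml_id("G_", g), "fbc:label" = g)
  }
  # reactions
  lr <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_len(nrow(rx))) {
    rnode <- xml2::xml_add_child(
      lr, "reaction", id = .sbml_id("R_", rx$id[j]), name = rx$name[j],
      reversible = tolower(as.character(rx$reversible[j])), fast = "false",
      "fbc:lowerFluxBound" = pid[[key_of(rx$lower_bound[j])]],
      "fbc:upperFluxBound" = pid[[key_of(rx$upper_bound[j])]])
    if (nzchar(rx$subsystem[j]) || nzchar(rx$ec[j])) {
      notes <- xml2::xml_add_child(rnode, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = .XHTML_NS)
      if (nzchar(rx$subsystem[j])) {
        xml2::xml_add_child(body, "p",
                            paste0("SUBSYSTEM: ", rx$subsystem[j]))
      }
      if (nzchar(rx$ec[j])) {
        xml2::xml_add_child(body, "p", paste0("EC Number: ", rx$ec[j]))
      }
    }
    st <- rx$stoichiometry[[j]]
    reac <- st[st < 0]; prod <- st[st > 0]
    if (length(reac)) {
      lrn <- xml2::xml_add_child(rnode, "listOfReactants")
      for (mi in names(reac)) {
        xml2::xml_add_child(lrn, "speciesReference",
                            species = .sbml_id("M_", mi),
                            stoichiometry = format(-reac[[mi]], digits = 17),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpn <- xml2::xml_add_child(rnode, "listOfProducts")
      for (mi in names(prod)) {
        xml2::xml_add_child(lpn, "speciesReference",
                            species = .sbml_id("M_", mi),
                            stoichiometry = format(prod[[mi]], digits = 17),
                            constant = "true")
      }
    }
    if (!gpr_is_empty(rx$gpr_rule[[j]])) {
      ga <- xml2::xml_add_child(rnode, "fbc:geneProductAssociation")
      .sbml_write_gpr(ga, unclass(rx$gpr_rule[[j]]))
    }
  }
  # objective
  if (length(model$objective)) {
    lo <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
    on <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj",
                              "fbc:type" = "maximize")
    lf <- xml2::xml_add_child(on, "fbc:listOfFluxObjectives")
    for (rid in names(model$objective)) {
      xml2::xml_add_child(lf, "fbc:fluxObjective",
                          "fbc:reaction" = .sbml_id("R_", rid),
                          "fbc:coefficient" =
                            format(model$objective[[rid]], digits = 17))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

.sbml_write_gpr <- function(parent, node) {
  if (node$op == "gene") {
    xml2::xml_add_child(parent, "fbc:geneProductRef",
                        "fbc:geneProduct" = .sbml_id("G_", node$gene))
  } else {
    child <- xml2::xml_add_child(parent, paste0("fbc:", node$op))
    for (a in node$args) .sbml_write_gpr(child, a)
  }
}

.read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e)))
  fnd <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  # gene products: map sanitized id -> label (original id)
  gmap <- character()
  for (gp in fnd(doc, "geneProduct")) {
    gid <- .attr_any(gp, "id")
    lab <- .attr_any(gp, "label")
    gmap[gid] <- if (!is.na(lab) && nzchar(lab)) lab
                 else .strip_prefix(gid, "G_")
  }
  # flux-bound parameters
  pmap <- numeric()
  for (p in fnd(doc, "parameter")) {
    pmap[xml2::xml_attr(p, "id")] <- as.numeric(xml2::xml_attr(p, "value"))
  }
  mets <- do.call(rbind, lapply(fnd(doc, "species"), function(sp) {
    id <- xml2::xml_attr(sp, "id")
    if (is.na(id)) stop("SBML parse error: species without an 'id'")
    nm <- xml2::xml_attr(sp, "name")
    data.frame(id = .strip_prefix(id, "M_"),
               name = if (is.na(nm)) .strip_prefix(id, "M_") else nm,
               compartment = xml2::xml_attr(sp, "compartment"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(mets)) stop("SBML parse error: no species found")
  rnodes <- fnd(doc, "reaction")
  if (length(rnodes) == 0L) stop("SBML parse error: no reactions found")
  missing_bounds <- character()
  rows <- vector("list", length(rnodes))
  stoichs <- vector("list", length(rnodes))
  for (j in seq_along(rnodes)) {
    rn <- rnodes[[j]]
    rid_raw <- xml2::xml_attr(rn, "id")
    if (is.na(rid_raw)) stop("SBML parse error: reaction without an 'id'")
    rid <- .strip_prefix(rid_raw, "R_")
    rev <- identical(xml2::xml_attr(rn, "reversible"), "true")
    lbp <- .attr_any(rn, "lowerFluxBound")
    ubp <- .attr_any(rn, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || !lbp %in% names(pmap) ||
        !ubp %in% names(pmap)) {
      missing_bounds <- c(missing_bounds, rid)
      lb <- if (rev) -1000 else 0
      ub <- 1000
    } else {
      lb <- pmap[[lbp]]; ub <- pmap[[ubp]]
    }
    st <- numeric()
    for (sr in fnd(rn, "speciesReference")) {
      sp <- .strip_prefix(xml2::xml_attr(sr, "species"), "M_")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      in_products <- identical(
        xml2::xml_name(xml2::xml_parent(sr)), "listOfProducts")
      st[sp] <- (if (in_products) 1 else -1) * coef +
        (if (sp %in% names(st)) st[[sp]] else 0)
    }
    subsystem <- ""; ec <- ""
    for (p in fnd(rn, "p")) {
      txt <- xml2::xml_text(p)
      if (grepl("^\\s*SUBSYSTEM:", txt)) {
        subsystem <- trimws(sub("^\\s*SUBSYSTEM:", "", txt))
      }
      if (grepl("^\\s*EC Number:", txt)) {
        ec <- trimws(sub("^\\s*EC Number:", "", txt))
      }
    }
    ga <- fnd(rn, "geneProductAssociation")
    gpr <- if (length(ga)) {
      .sbml_read_gpr(xml2::xml_children(ga[[1]])[[1]], gmap)
    } else ""
    rows[[j]] <- data.frame(
      id = rid, name = xml2::xml_attr(rn, "name"), lower_bound = lb,
      upper_bound = ub, reversible = lb < 0, subsystem = subsystem,
      ec = ec, gpr = gpr, stringsAsFactors = FALSE)
    stoichs[[j]] <- st
  }
  if (length(missing_bounds)) {
    warning("SBML reactions without fbc flux bounds use defaults ",
            "(-1000, 1000) if reversible else (0, 1000): ",
            paste(missing_bounds, collapse = ", "))
  }
  rx <- do.call(rbind, rows)
  rx$name[is.na(rx$name)] <- rx$id[is.na(rx$name)]
  rx$stoichiometry <- stoichs
  obj <- numeric()
  for (fo in fnd(doc, "fluxObjective")) {
    rid <- .strip_prefix(.attr_any(fo, "reaction"), "R_")
    coef <- as.numeric(.attr_any(fo, "coefficient"))
    obj[rid] <- if (is.na(coef)) 1 else coef
  }
  metabolic_model(mets, rx, genes = unname(gmap), objective = obj)
}

.sbml_read_gpr <- function(node, gmap) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- .attr_any(node, "geneProduct")
    return(if (gid %in% names(gmap)) gmap[[gid]]
           else .strip_prefix(gid, "G_"))
  }
  if (nm %in% c("and", "or")) {
    parts <- vapply(xml2::xml_children(node), .sbml_read_gpr,
                    character(1), gmap = gmap)
    return(paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")"))
  }
  stop("SBML parse error: unexpected element '", nm,
       "' in geneProductAssociation")
}
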