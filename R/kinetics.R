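#' Turnover-number (Kcat) tables
#'
#' A Kcat table holds turnover-number records keyed by reaction id or EC
#' number. A key may carry several records (different substrates, assay
#' conditions or source species); lookup returns the median value over all
#' matching records. Reaction-id records take precedence over EC records,
#' and a reaction annotated with several EC numbers pools the records of
#' all of them before taking the median.
#'
#' @param table data.frame with columns `key` (EC number or reaction id),
#'   `kcat` (1/s, positive), and optionally `species` and `provenance`
#'   (`"measured-human"` or `"other-species"`).
#' @return a validated `kcat_table` (data.frame subclass).
#' @export
kcat_table <- function(table) {
  table <- as.data.frame(table)
  stopifnot(all(c("key", "kcat") %in% names(table)))
  if (!"species" %in% names(table)) table$species <- "Homo sapiens"
  if (!"provenance" %in% names(table)) table$provenance <- "measured-human"
  if (any(!is.finite(table$kcat)) || any(table$kcat <= 0)) {
    stop("all kcat values must be finite and > 0")
  }
  class(table) <- c("kcat_table", "data.frame")
  table
}

#' @rdname kcat_table
#' @param path TSV with columns `key`, `kcat_per_s`, `species`, `source`.
#' @export
read_kcat_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("kcat_per_s" %in% names(tab)) tab$kcat <- tab$kcat_per_s
  if ("source" %in% names(tab)) tab$provenance <- tab$source
  kcat_table(tab)
}

#' Look up the Kcat of a reaction
#'
#' @param kcats a `kcat_table`.
#' @param reaction_id reaction id (checked first).
#' @param ec EC annotation; several numbers may be separated by `;`, `,`
#'   or whitespace, in which case all their records are pooled.
#' @return the median Kcat (1/s), or `NA` when no record matches.
#' @export
kcat_lookup <- function(kcats, reaction_id, ec = "") {
  hit <- kcats$kcat[kcats$key == reaction_id]
  if (length(hit)) return(stats::median(hit))
  if (!is.na(ec) && nzchar(ec)) {
    ecs <- strsplit(ec, "[;,[:space:]]+")[[1]]
    hit <- kcats$kcat[kcats$key %in% ecs]
    if (length(hit)) return(stats::median(hit))
  }
  NA_real_
}

#' Estimate the protein/mRNA scale (alpha/gamma ratio) per gene
#'
#' Under a steady-state synthesis/degradation balance
#' `dE/dt = alpha*M - gamma*E = 0`, enzyme abundance is proportional to
#' transcript abundance: `E = (alpha/gamma) * M`. The ratio is estimated
#' per gene as the median of protein/mRNA across reference tissues;
#' tissues with missing or zero mRNA for a gene are skipped for that gene.
#' Genes with no usable tissue fall back to the global median ratio and
#' are flagged.
#'
#' @param mrna gene x tissue matrix of transcript abundance (FPKM).
#' @param protein gene x tissue matrix of protein concentration (nmol/L),
#'   same genes and tissues.
#' @return a `protein_ratio_table`: data.frame with columns `gene`,
#'   `ratio`, `fallback` (logical), plus the global fallback ratio in
#'   `attr(, "global_ratio")`.
#' @export
estimate_alpha_gamma <- function(mrna, protein) {
  mrna <- as.matrix(mrna); protein <- as.matrix(protein)
  stopifnot(identical(dim(mrna), dim(protein)),
            identical(rownames(mrna), rownames(protein)))
  ratios <- rep(NA_real_, nrow(mrna))
  for (i in seq_len(nrow(mrna))) {
    use <- is.finite(mrna[i, ]) & is.finite(protein[i, ]) & mrna[i, ] > 0
    if (any(use)) ratios[i] <- stats::median(protein[i, use] / mrna[i, use])
  }
  if (all(is.na(ratios))) {
    stop("no gene has a usable tissue (nonzero mRNA with matched protein)")
  }
  global <- stats::median(ratios, na.rm = TRUE)
  out <- data.frame(gene = rownames(mrna), ratio = ratios,
                    fallback = is.na(ratios), stringsAsFactors = FALSE)
  out$ratio[out$fallback] <- global
  attr(out, "global_ratio") <- global
  class(out) <- c("protein_ratio_table", "data.frame")
  out
}

#' Build a ratio table directly from known values
#' @param ratios named numeric vector (gene -> alpha/gamma ratio).
#' @param global_ratio fallback for genes absent from `ratios`; defaults
#'   to the median of `ratios`.
#' @return a `protein_ratio_table`.
#' @export
protein_ratio_table <- function(ratios, global_ratio = NULL) {
  stopifnot(all(ratios > 0))
  if (is.null(global_ratio)) global_ratio <- stats::median(ratios)
  out <- data.frame(gene = names(ratios), ratio = unname(ratios),
                    fallback = FALSE, stringsAsFactors = FALSE)
  attr(out, "global_ratio") <- global_ratio
  class(out) <- c("protein_ratio_table", "data.frame")
  out
}

#' Predict enzyme abundance from transcript abundance
#'
#' Applies `E = (alpha/gamma) * M` gene by gene. Genes absent from the
#' ratio table use its global fallback ratio.
#'
#' @param expr named numeric vector of transcript abundance (FPKM) for one
#'   sample; names are gene ids.
#' @param ratios a `protein_ratio_table`.
#' @return named numeric vector of enzyme abundance E (nmol/L).
#' @export
estimate_enzyme_abundance <- function(expr, ratios) {
  stopifnot(!is.null(names(expr)), all(expr >= 0 | is.na(expr)))
  r <- ratios$ratio[match(names(expr), ratios$gene)]
  r[is.na(r)] <- attr(ratios, "global_ratio")
  stats::setNames(r * as.numeric(expr), names(expr))
}

#' Effective enzyme abundance of a reaction through its GPR rule
#'
#' Isozymes add and complex subunits limit: an `or` node sums its
#' children, an `and` node takes their minimum, a leaf reads the gene's
#' abundance. Genes missing from `abundance` contribute 0 (conservative
#' for complexes, neutral for isozymes). The empty rule returns `Inf`,
#' the "unlimited" marker.
#'
#' @param rule a `gpr_rule` (or rule text, parsed on the fly).
#' @param abundance named numeric vector, gene -> E (nmol/L).
#' @return effective abundance (nmol/L), or `Inf` for the empty rule.
#' @export
#' @examples
#' effective_enzyme(parse_gpr("(g1 and g2) or g3"),
#'                  c(g1 = 2, g2 = 5, g3 = 1))  # min(2,5) + 1 = 3
effective_enzyme <- function(rule, abundance) {
  if (is.character(rule)) rule <- parse_gpr(rule)
  if (gpr_is_empty(rule)) return(Inf)
  ev <- function(node) {
    switch(node$op,
      gene = if (node$gene %in% names(abundance))
               max(abundance[[node$gene]], 0) else 0,
      and = min(vapply(node$args, ev, numeric(1))),
      or = sum(vapply(node$args, ev, numeric(1))))
  }
  ev(unclass(rule))
}

#' Essential oxidative-phosphorylation reactions left unbounded
#'
#' These respiratory-chain and ATP-synthase reactions are catalyzed by
#' complexes of 20+ subunits; a single missing abundance or Kcat record
#' would zero them out and silence respiration entirely, so their kinetic
#' caps are not applied.
#' @export
oxphos_whitelist <- c("ATPS4mi", "CYOOm2i", "CYOR_u10mi", "NADH2_u10mi",
                      "r0205", "CYOOm3i", "FADH2ETC", "GLYC3PFADm")

#' Derive per-reaction Vmax bounds from enzyme abundance and Kcat
#'
#' For every enzymatic reaction with a Kcat record and a nonempty GPR,
#' `Vmax [mmol/L/min] = Kcat [1/s] * 60 * E [nmol/L] * 1e-6` with E the
#' effective abundance through the GPR. Reactions lacking a Kcat record or
#' a GPR, and whitelisted reactions, are unlimited (`Inf`).
#'
#' @param model a `metabolic_model`.
#' @param abundance named numeric vector, gene -> E (nmol/L).
#' @param kcats a `kcat_table`.
#' @param whitelist reaction ids exempted from kinetic caps; defaults to
#'   [oxphos_whitelist].
#' @param sample sample id stored in the result.
#' @return a `kinetic_context`: list with `sample`, `abundance`, and
#'   `vmax` (named vector over all reactions; `Inf` = unlimited). The
#'   fraction of enzymatic reactions capped is reported via `message()`.
#' @export
reaction_vmax <- function(model, abundance, kcats,
                          whitelist = oxphos_whitelist, sample = "sample") {
  validate_model(model)
  rx <- model$reactions
  comp <- classify_reactions(model)
  vmax <- rep(Inf, nrow(rx))
  names(vmax) <- rx$id
  for (j in seq_len(nrow(rx))) {
    if (rx$id[j] %in% whitelist) next
    if (gpr_is_empty(rx$gpr_rule[[j]])) next
    kc <- kcat_lookup(kcats, rx$id[j], rx$ec[j])
    if (is.na(kc)) next
    e_eff <- effective_enzyme(rx$gpr_rule[[j]], abundance)
    vmax[j] <- if (is.finite(e_eff)) kc * 60 * e_eff * 1e-6 else Inf
  }
  enz <- names(comp)[comp == "enzymatic"]
  n_capped <- sum(is.finite(vmax[enz]))
  message(sprintf("kinetic caps on %d/%d enzymatic reactions (%.1f%%)",
                  n_capped, length(enz),
                  if (length(enz)) 100 * n_capped / length(enz) else 0))
  structure(list(sample = sample, abundance = abundance, vmax = vmax),
            class = "kinetic_context")
}

#' @export
print.kinetic_context <- function(x, ...) {
  cat("<kinetic_context> sample ", x$sample, ": ",
      sum(is.finite(x$vmax)), "/", length(x$vmax),
      " reactions kinetically capped\n", sep = "")
  invisible(x)
}

#' Read an exchange/uptake configuration
#'
#' @param path TSV with columns `exchange_id`, `category` (one of
#'   `nutrient`, `essential_amino_acid`, `cofactor`, `iron_oxygen`),
#'   `uptake_bound` (mmol/L/min, used for `nutrient`), and optionally
#'   `secretion_bound`.
#' @return data.frame for [apply_kinetic_bounds()].
#' @export
read_uptake_config <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Constrain a model with kinetic caps and uptake bounds
#'
#' Interior reactions with a finite Vmax get `upper_bound <- min(existing,
#' Vmax)`; reversible ones are additionally capped symmetrically at
#' `lower_bound <- max(existing, -Vmax)`. Exchange reactions get uptake
#' bounds from the configuration: `nutrient` rows use their literature
#' `uptake_bound`, `essential_amino_acid` rows use a small default uptake,
#' and `cofactor`/`iron_oxygen` rows are unlimited (uptake bound 1000).
#' A `secretion_bound` column, when present and finite, caps the positive
#' direction. Apart from the uptake configuration, bounds are never
#' widened.
#'
#' @param model a `metabolic_model`.
#' @param context a `kinetic_context` covering the model's reactions.
#' @param uptake_config data.frame from [read_uptake_config()], or `NULL`
#'   to leave exchange bounds untouched.
#' @param essential_aa_uptake uptake bound (mmol/L/min) for
#'   `essential_amino_acid` rows; the literature gives no value, 0.01 is
#'   the package default.
#' @return a new `metabolic_model` with per-sample bounds.
#' @export
apply_kinetic_bounds <- function(model, context, uptake_config = NULL,
                                 essential_aa_uptake = 0.01) {
  stopifnot(inherits(context, "kinetic_context"))
  missing_rxn <- setdiff(model$reactions$id, names(context$vmax))
  if (length(missing_rxn)) {
    stop("kinetic context lacks reaction(s): ",
         paste(missing_rxn, collapse = ", "))
  }
  rx <- model$reactions
  bnd <- .is_boundary(model)
  vmax <- context$vmax[rx$id]
  for (j in seq_len(nrow(rx))) {
    if (bnd[j] || !is.finite(vmax[j])) next
    rx$upper_bound[j] <- min(rx$upper_bound[j], vmax[j])
    if (rx$reversible[j]) rx$lower_bound[j] <- max(rx$lower_bound[j], -vmax[j])
  }
  if (!is.null(uptake_config)) {
    for (k in seq_len(nrow(uptake_config))) {
      i <- match(uptake_config$exchange_id[k], rx$id)
      if (is.na(i) || !bnd[i]) {
        warning("uptake config names absent exchange reaction '",
                uptake_config$exchange_id[k], "'; skipped")
        next
      }
      cat_k <- gsub("[-/ ]", "_", tolower(uptake_config$category[k]))
      uptake <- switch(cat_k,
        nutrient = as.numeric(uptake_config$uptake_bound[k]),
        essential_amino_acid = essential_aa_uptake,
        cofactor = 1000,
        iron_oxygen = 1000,
        stop("unknown uptake category: ", uptake_config$category[k]))
      rx$lower_bound[i] <- -uptake
      if ("secretion_bound" %in% names(uptake_config)) {
        sec <- suppressWarnings(
          as.numeric(uptake_config$secretion_bound[k]))
        if (is.finite(sec)) rx$upper_bound[i] <- sec
      }
    }
  }
  rx$reversible <- rx$lower_bound < 0
  model$reactions <- rx
  validate_model(model)
  model
}
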