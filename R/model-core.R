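#' Construct a constraint-based metabolic model
#'
#' A `metabolic_model` bundles a stoichiometric matrix with flux bounds,
#' gene-protein-reaction (GPR) rules and a biomass objective. The sign
#' convention is the standard constraint-based one: a negative flux through
#' an exchange reaction is uptake into the cell, a positive flux is
#' secretion. Fluxes are in mmol per gram dry weight per hour.
#'
#' @param S stoichiometric matrix (metabolites x reactions) with dimnames;
#'   negative coefficients mark consumed metabolites.
#' @param lb,ub flux bounds per reaction (named or in column order of `S`).
#' @param objective reaction id of the objective (typically biomass).
#' @param gpr character vector of GPR rule strings per reaction (`""` means
#'   the reaction is unconditionally available).
#' @param metabolite_name,compartment optional per-metabolite annotation.
#' @param genes gene ids; defaults to the genes referenced by `gpr`.
#'
#' @return An object of class `metabolic_model` with fields `S`, `lb`, `ub`,
#'   `gpr`, `genes`, `objective`, `is_exchange`, `metabolites`.
#' @export
#' @examples
#' S <- cbind(EX_A = c(A = -1, B = 0), R1 = c(-1, 1), BIO = c(0, -1))
#' m <- metabolic_model(S, lb = c(-10, 0, 0), ub = c(0, 1000, 1000),
#'                      objective = "BIO")
#' m
metabolic_model <- function(S, lb, ub, objective, gpr = NULL,
                            metabolite_name = NULL, compartment = NULL,
                            genes = NULL) {
  S <- as.matrix(S)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("S must have metabolite row names and reaction column names")
  }
  n <- ncol(S)
  if (is.null(gpr)) gpr <- rep("", n)
  lb <- unname(if (!is.null(names(lb))) lb[colnames(S)] else lb)
  ub <- unname(if (!is.null(names(ub))) ub[colnames(S)] else ub)
  stopifnot(length(lb) == n, length(ub) == n, length(gpr) == n)
  mets <- data.frame(
    id = rownames(S),
    name = if (is.null(metabolite_name)) rownames(S) else metabolite_name,
    compartment = if (is.null(compartment)) "c" else compartment,
    stringsAsFactors = FALSE
  )
  rule_genes <- unique(unlist(lapply(gpr, function(g) {
    if (!nzchar(g)) character(0) else gpr_genes(parse_gpr(g))
  })))
  if (is.null(genes)) genes <- rule_genes
  obj <- list(
    S = S,
    lb = as.numeric(lb),
    ub = as.numeric(ub),
    gpr = as.character(gpr),
    genes = sort(unique(as.character(genes))),
    objective = objective,
    # the biomass drain is structurally a boundary reaction but not an
    # exchange with the environment
    is_exchange = detect_exchanges(S) & colnames(S) != objective,
    metabolites = mets
  )
  class(obj) <- "metabolic_model"
  validate_model(obj)
  obj
}

# single-metabolite boundary reactions, by convention with coefficient -1
detect_exchanges <- function(S) {
  apply(S != 0, 2, sum) == 1L & apply(S, 2, min) == -1
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf(
    "metabolic_model: %d metabolites, %d reactions (%d exchanges), %d genes\n",
    nrow(x$S), ncol(x$S), sum(x$is_exchange), length(x$genes)))
  cat(sprintf("objective: %s\n", x$objective))
  invisible(x)
}

#' Validate the structural invariants of a metabolic model
#'
#' Checks that bounds are ordered, the objective reaction exists, every
#' GPR-referenced gene is in the gene set, and exchange reactions follow
#' the single-metabolite, coefficient -1 convention.
#'
#' @param model a `metabolic_model`.
#' @return The model, invisibly; errors describe the offending element.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rxns <- colnames(model$S)
  if (anyDuplicated(rxns)) stop("duplicated reaction ids")
  if (anyDuplicated(rownames(model$S))) stop("duplicated metabolite ids")
  bad <- which(model$lb > model$ub)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rxns[bad], collapse = ", "))
  }
  if (!model$objective %in% rxns) {
    stop("objective reaction '", model$objective, "' is not in the model")
  }
  rule_genes <- unique(unlist(lapply(model$gpr, function(g) {
    if (!nzchar(g)) character(0) else gpr_genes(parse_gpr(g))
  })))
  missing <- setdiff(rule_genes, model$genes)
  if (length(missing)) {
    stop("GPR rules reference gene(s) outside the gene set: ",
         paste(missing, collapse = ", "))
  }
  single <- which(colSums(model$S != 0) == 1L)
  for (j in single) {
    coefv <- model$S[model$S[, j] != 0, j]
    if (model$is_exchange[j] && !isTRUE(all.equal(unname(coefv), -1))) {
      stop("exchange reaction '", rxns[j],
           "' must have a single metabolite with coefficient -1")
    }
  }
  invisible(model)
}

#' Load a metabolic model from file
#'
#' Reads either an SBML Level 3 document with the FBC package (bounds held
#' in parameters, GPR rules in `fbc:geneProductAssociation`, objective in
#' the active `fbc:objective`) or the package's plain-JSON toy dialect.
#' Exchange reactions are auto-detected as single-metabolite boundary
#' reactions.
#'
#' @param path file path.
#' @param dialect `"sbml-fbc"` or `"toy-json"`; default guesses from the
#'   file extension.
#' @return A validated [metabolic_model()].
#' @export
load_model <- function(path, dialect = c("auto", "sbml-fbc", "toy-json")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) %in% c("xml", "sbml")) {
      "sbml-fbc"
    } else "toy-json"
  }
  switch(dialect,
         "toy-json" = read_toy_json(path),
         "sbml-fbc" = read_sbml_fbc(path))
}

read_toy_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed toy-json model: ", conditionMessage(e))
  )
  for (field in c("metabolites", "reactions", "objective")) {
    if (is.null(doc[[field]])) stop("toy-json model lacks '", field, "'")
  }
  met_ids <- vapply(doc$metabolites, function(m) {
    if (is.character(m)) m else m$id
  }, character(1))
  met_name <- vapply(doc$metabolites, function(m) {
    if (is.character(m)) m else if (is.null(m$name)) m$id else m$name
  }, character(1))
  met_comp <- vapply(doc$metabolites, function(m) {
    if (is.character(m)) "c" else if (is.null(m$compartment)) "c" else m$compartment
  }, character(1))
  n <- length(doc$reactions)
  S <- matrix(0, nrow = length(met_ids), ncol = n,
              dimnames = list(met_ids, vapply(doc$reactions, `[[`, "", "id")))
  lb <- ub <- numeric(n)
  gpr <- character(n)
  for (j in seq_len(n)) {
    r <- doc$reactions[[j]]
    st <- r$stoich
    unknown <- setdiff(names(st), met_ids)
    if (length(unknown)) {
      stop("reaction '", r$id, "' references unknown metabolite(s): ",
           paste(unknown, collapse = ", "))
    }
    S[names(st), j] <- vapply(st, as.numeric, numeric(1))
    lb[j] <- if (is.null(r$lb)) -1000 else as.numeric(r$lb)
    ub[j] <- if (is.null(r$ub)) 1000 else as.numeric(r$ub)
    gpr[j] <- if (is.null(r$gpr)) "" else r$gpr
  }
  metabolic_model(S, lb, ub, objective = doc$objective, gpr = gpr,
                  metabolite_name = met_name, compartment = met_comp)
}

#' Write a metabolic model to file
#'
#' Inverse of [load_model()]; both dialects round-trip to the same model up
#' to reaction ordering.
#'
#' @param model a `metabolic_model`.
#' @param path output path.
#' @param dialect `"toy-json"` (default) or `"sbml-fbc"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("toy-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  if (dialect == "toy-json") {
    rxns <- lapply(seq_len(ncol(model$S)), function(j) {
      nz <- which(model$S[, j] != 0)
      list(id = colnames(model$S)[j],
           stoich = as.list(stats::setNames(model$S[nz, j],
                                            rownames(model$S)[nz])),
           lb = model$lb[j], ub = model$ub[j], gpr = model$gpr[j])
    })
    doc <- list(
      metabolites = lapply(seq_len(nrow(model$metabolites)), function(i) {
        as.list(model$metabolites[i, ])
      }),
      reactions = rxns,
      objective = model$objective
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(sbml_fbc_text(model), path)
  }
  invisible(path)
}

# ---- GPR rules -------------------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Parses a boolean rule over gene ids with `and`, `or` (case-insensitive)
#' and parentheses into an abstract syntax tree. The empty rule parses to an
#' expression that is always true (reaction unconditionally available).
#'
#' @param text rule string, e.g. `"(G1 and G2) or G3"`.
#' @return A `gpr_expression`: nested lists with nodes
#'   `list(op = "and"/"or", args = ...)`, `list(op = "gene", id = ...)` or
#'   `list(op = "true")`.
#' @export
#' @examples
#' eval_gpr(parse_gpr("(G1 and G2) or G3"), deleted = "G2")  # TRUE via G3
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- gpr_tokenize(text)
  if (length(toks$type) == 0L) {
    return(structure(list(op = "true"), class = "gpr_expression"))
  }
  st <- new.env(parent = emptyenv())
  st$pos <- 1L
  peek <- function() if (st$pos > length(toks$type)) "" else toks$type[st$pos]
  take <- function() {
    i <- st$pos; st$pos <- st$pos + 1L
    list(type = toks$type[i], value = toks$value[i], at = toks$at[i])
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (peek() == "or") { take(); args <- c(args, list(parse_and())) }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (peek() == "and") { take(); args <- c(args, list(parse_atom())) }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_atom <- function() {
    tk <- take()
    if (identical(tk$type, "(")) {
      e <- parse_or()
      cl <- take()
      if (!identical(cl$type, ")")) {
        stop("GPR parse error: unbalanced parenthesis at position ", tk$at)
      }
      return(e)
    }
    if (identical(tk$type, "id")) return(list(op = "gene", id = tk$value))
    stop("GPR parse error: unexpected token '", tk$value,
         "' at position ", tk$at)
  }
  ast <- parse_or()
  if (st$pos <= length(toks$type)) {
    stop("GPR parse error: stray token '", toks$value[st$pos],
         "' at position ", toks$at[st$pos])
  }
  structure(ast, class = "gpr_expression")
}

gpr_tokenize <- function(text) {
  type <- character(0); value <- character(0); at <- integer(0)
  i <- 1L; nch <- nchar(text)
  while (i <= nch) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      type <- c(type, ch); value <- c(value, ch); at <- c(at, i)
      i <- i + 1L; next
    }
    m <- regmatches(substr(text, i, nch),
                    regexpr("^[A-Za-z0-9_.:-]+", substr(text, i, nch)))
    if (length(m) == 0L) {
      stop("GPR parse error: unexpected character '", ch,
           "' at position ", i)
    }
    tt <- switch(tolower(m), "and" = "and", "or" = "or", "id")
    type <- c(type, tt); value <- c(value, m); at <- c(at, i)
    i <- i + nchar(m)
  }
  list(type = type, value = value, at = at)
}

#' Evaluate a GPR expression under a set of gene deletions
#'
#' @param expr a `gpr_expression` from [parse_gpr()].
#' @param deleted character vector of deleted gene ids.
#' @return `TRUE` if the reaction remains available, else `FALSE`.
#' @export
eval_gpr <- function(expr, deleted = character(0)) {
  switch(expr$op,
         "true" = TRUE,
         "gene" = !(expr$id %in% deleted),
         "and" = all(vapply(expr$args, eval_gpr, logical(1), deleted = deleted)),
         "or" = any(vapply(expr$args, eval_gpr, logical(1), deleted = deleted)),
         stop("unknown GPR node: ", expr$op))
}

# all gene ids referenced by a parsed rule
gpr_genes <- function(expr) {
  switch(expr$op,
         "true" = character(0),
         "gene" = expr$id,
         unique(unlist(lapply(expr$args, gpr_genes))))
}

#' Knock genes out of a model
#'
#' Returns a copy of the model in which every reaction whose GPR rule
#' evaluates to false under the deletion set has both bounds set to zero;
#' all other bounds are untouched. GPR semantics are purely boolean (a
#' surviving isozyme keeps the reaction fully available).
#'
#' @param model a `metabolic_model`.
#' @param deleted character vector of gene ids; ids absent from the model's
#'   gene set trigger a warning and are ignored.
#' @return The constrained model.
#' @export
apply_gene_deletions <- function(model, deleted) {
  validate_model(model)
  deleted <- as.character(deleted)
  unknown <- setdiff(deleted, model$genes)
  if (length(unknown)) {
    warning("deletion of gene(s) not in the model (ignored): ",
            paste(unknown, collapse = ", "))
  }
  for (j in which(nzchar(model$gpr))) {
    if (!eval_gpr(parse_gpr(model$gpr[j]), deleted)) {
      model$lb[j] <- 0
      model$ub[j] <- 0
    }
  }
  model
}

# ---- media -----------------------------------------------------------------

#' Define a growth medium as exchange uptake bounds
#'
#' @param name medium label.
#' @param uptake_bounds named numeric vector: exchange reaction id to maximum
#'   uptake rate (nonnegative magnitude, mmol/gDW/h).
#' @return A `medium_definition`.
#' @export
medium_definition <- function(name, uptake_bounds) {
  uptake_bounds <- unlist(uptake_bounds)
  stopifnot(is.numeric(uptake_bounds), !is.null(names(uptake_bounds)))
  if (any(uptake_bounds < 0)) stop("uptake bounds must be nonnegative")
  structure(list(name = name, uptake_bounds = uptake_bounds),
            class = "medium_definition")
}

#' Read media definitions from a YAML config
#'
#' The file maps medium names to `{exchange_id: uptake_bound}` tables. The
#' package ships editable SDC and YPD presets in
#' `system.file("extdata/media/media.yaml", package = "serflux")`.
#'
#' @param path YAML file.
#' @return Named list of [medium_definition()] objects.
#' @export
read_media_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(nm) medium_definition(nm, cfg[[nm]]))
  stats::setNames(out, names(cfg))
}

#' Apply a medium to a model
#'
#' For each listed exchange the lower bound becomes minus the uptake bound
#' (uptake magnitude). With `closed_default = TRUE` every unlisted exchange
#' has its uptake disabled (lower bound 0); secretion upper bounds are never
#' touched.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium_definition()].
#' @param closed_default close all unlisted exchanges? Default `TRUE`.
#' @return The constrained model, with the medium name recorded in
#'   `attr(, "medium")`.
#' @export
apply_medium <- function(model, medium, closed_default = TRUE) {
  stopifnot(inherits(medium, "medium_definition"))
  validate_model(model)
  ids <- names(medium$uptake_bounds)
  rxns <- colnames(model$S)
  bad <- ids[!(ids %in% rxns) | !(model$is_exchange[match(ids, rxns)] %in% TRUE)]
  if (length(bad)) {
    stop("medium '", medium$name,
         "' references non-exchange or unknown reaction(s): ",
         paste(bad, collapse = ", "))
  }
  if (closed_default) {
    model$lb[model$is_exchange] <- pmax(model$lb[model$is_exchange], 0)
  }
  j <- match(ids, rxns)
  model$lb[j] <- -medium$uptake_bounds
  attr(model, "medium") <- medium$name
  model
}

#' Set the uptake bound of one exchange reaction
#'
#' @param model a `metabolic_model`.
#' @param exchange exchange reaction id.
#' @param uptake nonnegative uptake magnitude (mmol/gDW/h).
#' @param mode `"fixed"` pins the flux to exactly `-uptake`
#'   (lower = upper = -uptake); `"max"` only lowers the lower bound,
#'   allowing any uptake up to the given rate.
#' @return The modified model.
#' @export
set_exchange_bound <- function(model, exchange, uptake,
                               mode = c("fixed", "max")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(uptake), length(uptake) == 1L, uptake >= 0)
  j <- match(exchange, colnames(model$S))
  if (is.na(j) || !model$is_exchange[j]) {
    stop("'", exchange, "' is not an exchange reaction of the model")
  }
  if (mode == "fixed") {
    model$lb[j] <- -uptake
    model$ub[j] <- -uptake
  } else {
    model$lb[j] <- -uptake
  }
  model
}

#' Auxotrophy deletions of the SEY6210 laboratory strain
#'
#' The deletion set applied before flux scans to mirror the SEY6210
#' genotype (leu2, ura3, his3, trp1, lys2, suc2).
#'
#' @return Character vector of gene ids.
#' @export
sey6210_deletions <- function() {
  c("LEU2", "URA3", "HIS3", "TRP1", "LYS2", "SUC2")
}

# ---- SBML L3 + FBC ---------------------------------------------------------

read_sbml_fbc <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML: ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  model_node <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(model_node, "xml_missing")) stop("SBML file has no <model>")

  params <- xml2::xml_find_all(model_node, ".//s:listOfParameters/s:parameter", ns)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  spp <- xml2::xml_find_all(model_node, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(spp, "id")
  sp_name <- xml2::xml_attr(spp, "name")
  sp_name[is.na(sp_name)] <- sp_id[is.na(sp_name)]
  sp_comp <- xml2::xml_attr(spp, "compartment")
  sp_bound <- xml2::xml_attr(spp, "boundaryCondition") %in% "true"
  keep <- !sp_bound
  met_ids <- sp_id[keep]

  # FBC attributes are namespace-qualified in conforming files; accept both
  attr2 <- function(node, name) {
    v <- xml2::xml_attr(node, name)
    if (all(is.na(v))) v <- xml2::xml_attr(node, paste0("fbc:", name))
    v
  }

  gps <- xml2::xml_find_all(model_node,
                            ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gp_lab <- attr2(gps, "label"); gp_id <- attr2(gps, "id")
  gp_map <- stats::setNames(ifelse(is.na(gp_lab), gp_id, gp_lab), gp_id)

  gpa_text <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr2(node, "geneProduct")
      lab <- gp_map[ref]
      return(if (is.na(lab)) ref else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_text, character(1))
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(model_node, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rx)
  if (n == 0L) stop("SBML model has no reactions")
  rx_id <- xml2::xml_attr(rx, "id")
  S <- matrix(0, nrow = length(met_ids), ncol = n,
              dimnames = list(met_ids, rx_id))
  lb <- rep(-1000, n); ub <- rep(1000, n); gpr <- character(n)
  for (j in seq_len(n)) {
    node <- rx[[j]]
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (sp %in% met_ids) S[sp, j] <- S[sp, j] - coef
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      coef <- as.numeric(xml2::xml_attr(sr, "stoichiometry"))
      if (is.na(coef)) coef <- 1
      if (sp %in% met_ids) S[sp, j] <- S[sp, j] + coef
    }
    lbid <- attr2(node, "lowerFluxBound")
    ubid <- attr2(node, "upperFluxBound")
    if (!is.na(lbid) && lbid %in% names(pval)) lb[j] <- pval[[lbid]]
    if (!is.na(ubid) && ubid %in% names(pval)) ub[j] <- pval[[ubid]]
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    if (!inherits(gpa, "xml_missing")) {
      root <- xml2::xml_children(gpa)
      if (length(root)) gpr[j] <- gpa_text(root[[1]])
    }
  }

  fo <- xml2::xml_find_first(
    model_node,
    ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (inherits(fo, "xml_missing")) {
    stop("SBML-FBC validation error: no flux objective defined")
  }
  objective <- xml2::xml_attr(fo, "reaction")

  metabolic_model(S, lb, ub, objective = objective, gpr = gpr,
                  metabolite_name = sp_name[keep],
                  compartment = sp_comp[keep])
}

sbml_fbc_text <- function(model) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  param_lines <- character(0)
  bound_ids <- list()
  pidx <- 0L
  bound_id <- function(v) {
    key <- format(v, digits = 15)
    if (is.null(bound_ids[[key]])) {
      pidx <<- pidx + 1L
      id <- sprintf("fb_%d", pidx)
      bound_ids[[key]] <<- id
      param_lines <<- c(param_lines, sprintf(
        '      <parameter id="%s" value="%s" constant="true"/>',
        id, format(v, digits = 15)))
    }
    bound_ids[[key]]
  }
  gpr_xml <- function(expr, indent) {
    pad <- strrep(" ", indent)
    switch(expr$op,
           "gene" = sprintf('%s<fbc:geneProductRef fbc:geneProduct="%s"/>',
                            pad, expr$id),
           "and" = ,
           "or" = paste0(
             pad, "<fbc:", expr$op, ">\n",
             paste(vapply(expr$args, gpr_xml, "", indent + 2L),
                   collapse = "\n"),
             "\n", pad, "</fbc:", expr$op, ">"),
           stop("cannot serialize GPR node: ", expr$op))
  }
  rx_lines <- character(0)
  for (j in seq_len(ncol(model$S))) {
    lbid <- bound_id(model$lb[j]); ubid <- bound_id(model$ub[j])
    nz <- which(model$S[, j] != 0)
    reac <- nz[model$S[nz, j] < 0]
    prod <- nz[model$S[nz, j] > 0]
    body <- character(0)
    if (length(reac)) {
      body <- c(body, "        <listOfReactants>",
                sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                        rownames(model$S)[reac],
                        format(-model$S[reac, j], digits = 15)),
                "        </listOfReactants>")
    }
    if (length(prod)) {
      body <- c(body, "        <listOfProducts>",
                sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                        rownames(model$S)[prod],
                        format(model$S[prod, j], digits = 15)),
                "        </listOfProducts>")
    }
    if (nzchar(model$gpr[j])) {
      body <- c(body, "        <fbc:geneProductAssociation>",
                gpr_xml(unclass(parse_gpr(model$gpr[j])), 10L),
                "        </fbc:geneProductAssociation>")
    }
    rx_lines <- c(rx_lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(colnames(model$S)[j]),
      if (model$lb[j] < 0) "true" else "false", lbid, ubid),
      body, "      </reaction>")
  }
  comps <- unique(model$metabolites$compartment)
  genes <- model$genes
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="model" fbc:strict="true">',
    "    <listOfCompartments>",
    sprintf('      <compartment id="%s" constant="true"/>', comps),
    "    </listOfCompartments>",
    "    <listOfSpecies>",
    sprintf('      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            model$metabolites$id, esc(model$metabolites$name),
            model$metabolites$compartment),
    "    </listOfSpecies>",
    "    <listOfParameters>",
    param_lines,
    "    </listOfParameters>",
    "    <listOfReactions>",
    rx_lines,
    "    </listOfReactions>",
    if (length(genes)) c(
      "    <fbc:listOfGeneProducts>",
      sprintf('      <fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
              genes, genes),
      "    </fbc:listOfGeneProducts>") else character(0),
    "    <fbc:listOfObjectives fbc:activeObjective=\"obj\">",
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    "        <fbc:listOfFluxObjectives>",
    sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="1"/>',
            model$objective),
    "        </fbc:listOfFluxObjectives>",
    "      </fbc:objective>",
    "    </fbc:listOfObjectives>",
    "  </model>",
    "</sbml>")
}
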