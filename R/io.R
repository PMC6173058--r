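## Model readers/writers: SBML Level 3 with the fbc extension, and the
## BiGG-repository JSON dialect. Reversible reactions stay single columns
## with a negative lower bound; they are never split.

.DEFAULT_BOUND <- 1000

#' Load a constraint-based model
#'
#' Reads SBML Level 3 (with the flux-bounds/objective `fbc` extension) or
#' BiGG-style JSON. Conventional `R_`/`M_`/`G_` SBML id prefixes are
#' stripped so that ids match the JSON dialect. If the file declares no
#' active objective, `objectiveId` must be supplied.
#'
#' @param path model file.
#' @param format `"auto"` (by extension), `"sbml"` or `"json"`.
#' @param objectiveId objective reaction id, overriding/completing the
#'   file's declaration.
#' @return a validated [MetabolicModel-class].
#' @examples
#' path <- system.file("extdata", "e_coli_core.json", package = "ESSim")
#' m <- loadModel(path)
#' m
#' @export
loadModel <- function(path, format = c("auto", "sbml", "json"),
                      objectiveId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "sbml"
  }
  if (format == "json") .readJSONModel(path, objectiveId)
  else .readSBMLModel(path, objectiveId)
}

.readJSONModel <- function(path, objectiveId = NULL) {
  j <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                error = function(e) stop("malformed JSON model '", path,
                                         "': ", conditionMessage(e)))
  for (fld in c("metabolites", "reactions"))
    if (is.null(j[[fld]]))
      stop("malformed JSON model '", path, "': missing '", fld, "'")
  mets <- data.frame(
    id = vapply(j$metabolites, function(m) as.character(m$id), ""),
    name = vapply(j$metabolites, function(m)
      as.character(if (is.null(m$name)) m$id else m$name), ""),
    compartment = vapply(j$metabolites, function(m)
      as.character(if (is.null(m$compartment)) "" else m$compartment), ""),
    stringsAsFactors = FALSE)
  n <- length(j$reactions)
  rxns <- data.frame(
    id = vapply(j$reactions, function(r) as.character(r$id), ""),
    name = vapply(j$reactions, function(r)
      as.character(if (is.null(r$name)) r$id else r$name), ""),
    lower_bound = vapply(j$reactions, function(r)
      as.numeric(if (is.null(r$lower_bound)) -.DEFAULT_BOUND else r$lower_bound), 0),
    upper_bound = vapply(j$reactions, function(r)
      as.numeric(if (is.null(r$upper_bound)) .DEFAULT_BOUND else r$upper_bound), 0),
    gpr = vapply(j$reactions, function(r)
      as.character(if (is.null(r$gene_reaction_rule)) "" else r$gene_reaction_rule), ""),
    subsystem = vapply(j$reactions, function(r)
      as.character(if (is.null(r$subsystem)) "" else r$subsystem), ""),
    stringsAsFactors = FALSE)
  sto <- lapply(j$reactions, function(r)
    unlist(r$metabolites, use.names = TRUE))
  names(sto) <- rxns$id
  if (is.null(objectiveId)) {
    oc <- vapply(j$reactions, function(r)
      as.numeric(if (is.null(r$objective_coefficient)) 0 else r$objective_coefficient), 0)
    if (any(oc != 0)) objectiveId <- rxns$id[which(oc != 0)[1]]
  }
  if (is.null(objectiveId))
    stop("model '", path, "' declares no objective; supply objectiveId")
  genes <- vapply(j$genes, function(g) as.character(g$id), "")
  if (length(genes)) {
    leaves <- unique(unlist(lapply(rxns$gpr, function(g)
      gprGenes(parseGPR(g))), use.names = FALSE))
    orphan <- setdiff(leaves, genes)
    if (length(orphan))
      stop("model '", path, "': GPR rules reference undeclared genes: ",
           paste(orphan, collapse = ", "))
  }
  metabolicModel(if (is.null(j$id)) basename(path) else j$id,
                 mets, rxns, sto, objectiveId, genes)
}

.stripPrefix <- function(x, prefix) sub(paste0("^", prefix, "_"), "", x)

.readSBMLModel <- function(path, objectiveId = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
          fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (inherits(mdl, "xml_missing"))
    stop("malformed SBML '", path, "': no <model> element (SBML L3 expected)")
  attr1 <- function(node, a) {
    v <- xml2::xml_attr(node, a)
    v
  }
  # parameters (flux bound values)
  pars <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  parval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                     xml2::xml_attr(pars, "id"))
  # gene products
  gps <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gpid <- xml2::xml_attr(gps, "id")
  gplabel <- xml2::xml_attr(gps, "label")
  gplabel[is.na(gplabel)] <- gpid[is.na(gplabel)]
  gplabel <- .stripPrefix(gplabel, "G")
  names(gplabel) <- gpid
  # species
  sp <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  if (!length(sp)) stop("malformed SBML '", path, "': no species")
  mets <- data.frame(
    id = .stripPrefix(xml2::xml_attr(sp, "id"), "M"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  .stripPrefix(xml2::xml_attr(sp, "id"), "M"),
                  xml2::xml_attr(sp, "name")),
    compartment = ifelse(is.na(xml2::xml_attr(sp, "compartment")), "",
                         xml2::xml_attr(sp, "compartment")),
    stringsAsFactors = FALSE)
  # reactions
  rx <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("malformed SBML '", path, "': no reactions")
  parseGPA <- function(node) {
    name <- xml2::xml_name(node)
    if (name == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      lbl <- gplabel[ref]
      return(if (is.na(lbl)) .stripPrefix(ref, "G") else unname(lbl))
    }
    kids <- xml2::xml_children(node)
    list(op = if (name == "and") "and" else "or",
         args = lapply(kids, parseGPA))
  }
  ids <- character(length(rx)); nms <- character(length(rx))
  lbs <- numeric(length(rx)); ubs <- numeric(length(rx))
  gprs <- character(length(rx)); sto <- vector("list", length(rx))
  boundOf <- function(ref, default) {
    if (is.na(ref)) return(default)
    v <- parval[ref]
    if (is.na(v)) stop("malformed SBML '", path, "': flux bound parameter '",
                       ref, "' not found")
    unname(v)
  }
  for (k in seq_along(rx)) {
    r <- rx[[k]]
    rid0 <- xml2::xml_attr(r, "id")
    if (is.na(rid0)) stop("malformed SBML '", path, "': reaction without id")
    ids[k] <- .stripPrefix(rid0, "R")
    nm <- xml2::xml_attr(r, "name")
    nms[k] <- if (is.na(nm)) ids[k] else nm
    rev <- identical(xml2::xml_attr(r, "reversible"), "true")
    lbs[k] <- boundOf(xml2::xml_attr(r, "lowerFluxBound"),
                      if (rev) -.DEFAULT_BOUND else 0)
    ubs[k] <- boundOf(xml2::xml_attr(r, "upperFluxBound"), .DEFAULT_BOUND)
    coef <- numeric()
    for (side in c(-1, 1)) {
      lname <- if (side < 0) "listOfReactants" else "listOfProducts"
      refs <- xml2::xml_find_all(r, paste0("./s:", lname, "/s:speciesReference"), ns)
      if (length(refs)) {
        stc <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        stc[is.na(stc)] <- 1
        spid <- .stripPrefix(xml2::xml_attr(refs, "species"), "M")
        add <- setNames(side * stc, spid)
        for (nm2 in names(add)) coef[nm2] <- (if (nm2 %in% names(coef)) coef[nm2] else 0) + add[[nm2]]
      }
    }
    sto[[k]] <- coef
    gpa <- xml2::xml_find_first(r, "./fbc:geneProductAssociation/*", ns)
    gprs[k] <- if (inherits(gpa, "xml_missing")) "" else gprToString(parseGPA(gpa))
  }
  names(sto) <- ids
  if (is.null(objectiveId)) {
    act <- xml2::xml_attr(xml2::xml_find_first(
      mdl, ".//fbc:listOfObjectives", ns), "activeObjective")
    fo <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
    if (length(fo)) {
      coefs <- as.numeric(xml2::xml_attr(fo, "coefficient"))
      coefs[is.na(coefs)] <- 1
      rref <- .stripPrefix(xml2::xml_attr(fo, "reaction"), "R")
      nz <- which(coefs != 0)
      if (length(nz)) objectiveId <- rref[nz[1]]
    }
  }
  if (is.null(objectiveId) || is.na(objectiveId))
    stop("model '", path, "' declares no objective; supply objectiveId ",
         "(RAVEN-style files often omit it)")
  rxns <- data.frame(id = ids, name = nms, lower_bound = lbs,
                     upper_bound = ubs, gpr = gprs, subsystem = "",
                     stringsAsFactors = FALSE)
  mname <- xml2::xml_attr(mdl, "id")
  metabolicModel(if (is.na(mname)) basename(path) else mname,
                 mets, rxns, sto, objectiveId, unname(gplabel))
}

#' Serialize a model to BiGG-style JSON
#'
#' The same dialect [loadModel()] reads, so models round-trip.
#'
#' @param model a [MetabolicModel-class].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
writeModelJSON <- function(model, path) {
  stopifnot(is(model, "MetabolicModel"))
  S <- model@stoichiometry
  rxlist <- lapply(seq_len(nrow(model@reactions)), function(k) {
    r <- model@reactions[k, ]
    col <- S[, k]
    nz <- which(col != 0)
    out <- list(id = r$id, name = r$name,
                metabolites = as.list(setNames(col[nz], rownames(S)[nz])),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr, subsystem = r$subsystem)
    if (identical(r$id, model@objectiveId)) out$objective_coefficient <- 1
    out
  })
  obj <- list(
    id = model@modelId,
    metabolites = lapply(seq_len(nrow(model@metabolites)), function(k)
      as.list(model@metabolites[k, c("id", "name", "compartment")])),
    reactions = rxlist,
    genes = lapply(model@genes, function(g) list(id = g, name = g)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
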