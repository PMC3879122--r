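# Minimal SBML Level 3 Version 2 export of the reaction-centric view.
# Constant (environment-held) species are exported with the
# boundaryCondition flag so downstream tools keep them fixed.

expr_to_mathml <- function(e, doc_ns) {
  tag <- function(name, ...) {
    n <- xml2::xml_new_root(name)
    for (ch in list(...)) xml2::xml_add_child(n, ch)
    n
  }
  rec <- function(e) {
    if (is.numeric(e)) {
      n <- xml2::xml_new_root("cn")
      xml2::xml_set_text(n, format(e, digits = 17))
      return(n)
    }
    if (is.name(e)) {
      n <- xml2::xml_new_root("ci")
      xml2::xml_set_text(n, as.character(e))
      return(n)
    }
    if (is.call(e)) {
      op <- as.character(e[[1L]])
      opname <- switch(op, "+" = "plus", "-" = "minus", "*" = "times",
                       "/" = "divide",
                       stop("cannot export operator '", op, "' to MathML"))
      args <- lapply(as.list(e)[-1L], rec)
      return(do.call(tag, c(list("apply", xml2::xml_new_root(opname)), args)))
    }
    stop("cannot export expression to MathML: ", deparse(e))
  }
  rec(e)
}

#' Export a model to SBML Level 3
#'
#' Writes the reaction-centric view of the model as an SBML Level 3
#' Version 2 core document: one compartment, the species (constant species
#' flagged as boundary conditions), the parameters, and one reaction per
#' kinetic law with its rate expression as MathML.  Requires the `xml2`
#' package.
#'
#' @param model A `bp_model`.
#' @param path Output path (conventionally `.xml`).
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  if (!requireNamespace("xml2", quietly = TRUE))
    stop("SBML export requires the 'xml2' package")
  validate_bp_model(model)
  views <- reaction_views(model)

  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  mdl <- xml2::xml_add_child(doc, "model", id = "biopepa_model")

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = "cell", constant = "true",
                      spatialDimensions = "3", size = "1")

  lsp <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (s in species_names(model)) {
    const <- s %in% model$constant_species
    xml2::xml_add_child(
      lsp, "species", id = s, compartment = "cell",
      initialAmount = format(model$initial[[s]], digits = 17),
      hasOnlySubstanceUnits = "true",
      boundaryCondition = if (const) "true" else "false",
      constant = if (const) "true" else "false")
  }

  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (p in names(model$parameters))
    xml2::xml_add_child(lp, "parameter", id = p,
                        value = format(model$parameters[[p]], digits = 17),
                        constant = "true")

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (r in reaction_names(model)) {
    v <- views[[r]]
    rx <- xml2::xml_add_child(lr, "reaction", id = r, reversible = "false")
    if (length(v$reactants)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (s in names(v$reactants))
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = format(v$reactants[[s]]),
                            constant = "true")
    }
    if (length(v$products)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (s in names(v$products))
        xml2::xml_add_child(lpr, "speciesReference", species = s,
                            stoichiometry = format(v$products[[s]]),
                            constant = "true")
    }
    if (length(v$modifiers)) {
      lmo <- xml2::xml_add_child(rx, "listOfModifiers")
      for (s in v$modifiers)
        xml2::xml_add_child(lmo, "modifierSpeciesReference", species = s)
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    xml2::xml_add_child(math, expr_to_mathml(model$laws[[r]]$expr))
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
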