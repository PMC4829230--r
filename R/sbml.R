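## SBML export/import of the Lsr model. The writer emits SBML Level 3
## Version 1 with one reaction per registry term; extracellular species
## changes carry the cell/element volume ratio as an explicit (non-integer)
## stoichiometry so the loaded right-hand side matches lsr_rhs directly.

.sbml_species <- c("Ae", "Ai", "Ap", "M", "T")

.lsr_numeric_params <- c("K_synth", "V_ydgG", "basal", "K_basal", "k_phos",
                         "k_pK", "d_Ap", "V_ind", "K_ind", "a0", "a_M",
                         "k2", "hill_n", "d_M", "k_T", "d_T",
                         "activation_fold")

## MathML fragments for each registry term's kinetic law.
.mml <- list(
  ci = function(x) paste0("<ci> ", x, " </ci>"),
  ap = function(op, ...) paste0("<apply><", op, "/>",
                                paste0(c(...), collapse = ""), "</apply>")
)

.lsr_kinetic_mathml <- function(vr) {
  ci <- .mml$ci; ap <- .mml$ap
  mm <- function(vmax, s, km) ap("divide", ap("times", ci(vmax), ci(s)),
                                 ap("plus", ci(km), ci(s)))
  hill <- ap("divide",
             ap("power", ci("Ap"), ci("hill_n")),
             ap("plus", ap("power", ci("k2"), ci("hill_n")),
                ap("power", ci("Ap"), ci("hill_n"))))
  list(
    synthesis = ci("K_synth"),
    export = ap("times", ci("V_ydgG"), ci("Ai")),
    basal_import = mm("basal", "Ae", "K_basal"),
    induced_import = ap("times", ci("V_ind"), ci("T"),
                        ap("divide", ci("Ae"),
                           ap("plus", ci("K_ind"), ci("Ae")))),
    phosphorylation = ap("times",
                         ap("plus", ci("k_phos"),
                            ap("times", ci("k_pK"), ci("T"))),
                         ci("Ai")),
    ap_turnover = ap("times", ci("d_Ap"), ci("Ap")),
    transcription = ap("plus", ci("a0"), ap("times", ci("a_M"), hill)),
    mrna_decay = ap("times", ci("d_M"), ci("M")),
    translation = ap("times", ci("k_T"), ci("M")),
    protein_turnover = ap("times", ci("d_T"), ci("T"))
  )
}

.lsr_reaction_stoich <- function(vr) {
  lapply(lsr_terms(), function(term) {
    st <- term$stoich
    st["Ae"] <- st["Ae"] * vr
    st[st != 0]
  })
}

#' Write the Lsr model as SBML
#'
#' Emits SBML Level 3 Version 1: the five species, every rate constant as
#' a global parameter (plus any `extras`), and one reaction per registry
#' term with a MathML kinetic law. The cell/extracellular volume ratio is
#' carried in the extracellular stoichiometries and as the parameter
#' `volume_ratio`.
#'
#' @param params an [lsr_params()] object.
#' @param path output file path.
#' @param volume_ratio cell : extracellular volume ratio.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(params, path, volume_ratio = 1 / 24) {
  validate_lsr_params(params)
  y0 <- lsr_initial_state(params)
  sp <- paste(vapply(.sbml_species, function(s) sprintf(
    '      <species id="%s" compartment="%s" initialConcentration="%.17g" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    s, if (s == "Ae") "environment" else "cytosol", y0[[s]]),
    character(1)), collapse = "\n")
  pvals <- c(unlist(params[.lsr_numeric_params]),
             volume_ratio = volume_ratio, unlist(params$extras))
  pars <- paste(vapply(names(pvals), function(nm) sprintf(
    '      <parameter id="%s" value="%.17g" constant="true"/>',
    nm, pvals[[nm]]), character(1)), collapse = "\n")
  laws <- .lsr_kinetic_mathml(volume_ratio)
  stoichs <- .lsr_reaction_stoich(volume_ratio)
  rxn <- vapply(names(laws), function(nm) {
    st <- stoichs[[nm]]
    reac <- st[st < 0]; prod <- st[st > 0]
    refs <- function(v, tag) {
      if (length(v) == 0) return("")
      body <- paste(vapply(names(v), function(s) sprintf(
        '          <speciesReference species="%s" stoichiometry="%.17g" constant="true"/>',
        s, abs(v[[s]])), character(1)), collapse = "\n")
      sprintf("        <listOf%s>\n%s\n        </listOf%s>", tag, body, tag)
    }
    sprintf(paste0(
      '      <reaction id="%s" reversible="false">\n%s\n%s\n',
      '        <kineticLaw>\n',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">%s</math>\n',
      '        </kineticLaw>\n      </reaction>'),
      nm, refs(reac, "Reactants"), refs(prod, "Products"), laws[[nm]])
  }, character(1))
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">\n',
    '  <model id="lsr_ai2_circuit" name="Lsr AI-2 signaling circuit">\n',
    '    <listOfCompartments>\n',
    '      <compartment id="cytosol" spatialDimensions="3" size="1" constant="true"/>\n',
    '      <compartment id="environment" spatialDimensions="3" size="%.17g" constant="true"/>\n',
    '    </listOfCompartments>\n',
    '    <listOfSpecies>\n%s\n    </listOfSpecies>\n',
    '    <listOfParameters>\n%s\n    </listOfParameters>\n',
    '    <listOfReactions>\n%s\n    </listOfReactions>\n',
    '  </model>\n</sbml>\n'),
    1 / volume_ratio, sp, pars, paste(rxn, collapse = "\n"))
  writeLines(doc, path)
  invisible(path)
}

## Recursively convert a stripped MathML node to an R expression.
.mathml_to_expr <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (nm == "cn") return(as.numeric(trimws(xml2::xml_text(node))))
  if (nm == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("malformed MathML: math must wrap one node",
                                call. = FALSE)
    return(.mathml_to_expr(kids[[1]]))
  }
  if (nm != "apply") stop("unsupported MathML node: ", nm, call. = FALSE)
  kids <- xml2::xml_children(node)
  op <- xml2::xml_name(kids[[1]])
  args <- lapply(kids[-1], .mathml_to_expr)
  fun <- switch(op, plus = "+", minus = "-", times = "*",
                divide = "/", power = "^",
                stop("unsupported MathML operator: ", op, call. = FALSE))
  if (length(args) == 1 && op == "minus") return(call("-", args[[1]]))
  out <- args[[1]]
  for (a in args[-1]) out <- call(fun, out, a)
  out
}

#' Load an Lsr model from SBML
#'
#' Reads parameters, species and reactions (with MathML kinetic laws) and
#' reconstructs both an [lsr_params()] object and a generic right-hand-side
#' function assembled from reaction stoichiometry times evaluated kinetic
#' laws. The generic assembly is an independent evaluation path from
#' [lsr_rhs()], which the test suite exploits as a cross-check.
#'
#' @param path SBML file path.
#' @return list with `params` ([lsr_params()]), `volume_ratio`,
#'   `reactions` (id, stoichiometry, rate expression) and `rhs`
#'   (`function(state)` returning named derivatives).
#' @export
load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pnodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pv <- stats::setNames(
    as.numeric(xml2::xml_attr(pnodes, "value")),
    xml2::xml_attr(pnodes, "id"))
  missing <- setdiff(.lsr_numeric_params, names(pv))
  if (length(missing))
    stop("load_sbml: unmatched parameters: ",
         paste(missing, collapse = ", "), call. = FALSE)
  core <- as.list(pv[.lsr_numeric_params])
  extras <- as.list(pv[setdiff(names(pv),
                               c(.lsr_numeric_params, "volume_ratio"))])
  params <- do.call(lsr_params, c(core, list(extras = extras)))
  vr <- if ("volume_ratio" %in% names(pv)) pv[["volume_ratio"]] else 1 / 24

  snodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sids <- xml2::xml_attr(snodes, "id")
  missing_sp <- setdiff(.sbml_species, sids)
  if (length(missing_sp))
    stop("load_sbml: unmatched species: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)

  rnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rnodes, function(rn) {
    stoich <- stats::setNames(numeric(length(.sbml_species)), .sbml_species)
    for (ref in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      stoich[s] <- stoich[s] - as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    for (ref in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      s <- xml2::xml_attr(ref, "species")
      stoich[s] <- stoich[s] + as.numeric(xml2::xml_attr(ref, "stoichiometry"))
    }
    math <- xml2::xml_find_first(rn, "./kineticLaw/math")
    if (is.na(xml2::xml_name(math)))
      stop("load_sbml: reaction ", xml2::xml_attr(rn, "id"),
           " has no kinetic law", call. = FALSE)
    list(id = xml2::xml_attr(rn, "id"), stoich = stoich,
         rate = .mathml_to_expr(math))
  })

  penv <- list2env(as.list(pv), envir = new.env(parent = baseenv()))
  rhs <- function(state) {
    e <- list2env(as.list(state[.sbml_species]),
                  envir = new.env(parent = penv))
    d <- stats::setNames(numeric(length(.sbml_species)), .sbml_species)
    for (r in reactions) {
      rate <- eval(r$rate, envir = e)
      d <- d + rate * r$stoich
    }
    d
  }
  list(params = params, volume_ratio = vr, reactions = reactions, rhs = rhs)
}
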