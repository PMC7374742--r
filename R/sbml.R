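#' Read an SBML level-2 mass-action model
#'
#' Parses the mass-action subset of SBML level 2: species with initial
#' concentrations, compartments, global/local parameters, and reactions
#' whose kinetic law is a product of constants and reactant concentrations
#' (optionally a difference of a forward and a reverse such product for
#' reversible reactions). Any other rate law is rejected with an error
#' naming the reaction. Compartment sizes multiply into the rate constant.
#'
#' @param path path to an SBML file.
#' @return A [kinetic_model].
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (!length(sp_nodes)) stop("read_sbml: no species found")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_conc <- suppressWarnings(as.numeric(xml2::xml_attr(sp_nodes, "initialConcentration")))
  if (any(is.na(sp_conc))) {
    stop("read_sbml: missing initialConcentration for species ",
         paste(sp_id[is.na(sp_conc)], collapse = ", "))
  }
  species <- stats::setNames(sp_conc, sp_id)
  consts <- list()
  comp_nodes <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  for (nd in comp_nodes) {
    size <- suppressWarnings(as.numeric(xml2::xml_attr(nd, "size")))
    consts[[xml2::xml_attr(nd, "id")]] <- if (is.na(size)) 1 else size
  }
  for (nd in xml2::xml_find_all(doc, "./model/listOfParameters/parameter")) {
    consts[[xml2::xml_attr(nd, "id")]] <-
      as.numeric(xml2::xml_attr(nd, "value"))
  }
  reactions <- list()
  for (rn in xml2::xml_find_all(doc, ".//listOfReactions/reaction")) {
    rid <- xml2::xml_attr(rn, "id")
    get_refs <- function(xpath) {
      refs <- xml2::xml_find_all(rn, xpath)
      if (!length(refs)) return(stats::setNames(integer(0), character(0)))
      st <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
      st[is.na(st)] <- 1
      stats::setNames(as.integer(st), xml2::xml_attr(refs, "species"))
    }
    reactants <- get_refs("./listOfReactants/speciesReference")
    products <- get_refs("./listOfProducts/speciesReference")
    local <- consts
    for (nd in xml2::xml_find_all(rn, "./kineticLaw/listOfParameters/parameter")) {
      local[[xml2::xml_attr(nd, "id")]] <- as.numeric(xml2::xml_attr(nd, "value"))
    }
    math <- xml2::xml_find_first(rn, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) {
      stop("read_sbml: reaction ", rid, " has no kinetic law")
    }
    expr <- xml2::xml_children(math)
    if (length(expr) != 1) stop("read_sbml: malformed math in reaction ", rid)
    parsed <- parse_mass_action(expr[[1]], names(species), local, rid)
    same_counts <- function(counts, stoich) {
      length(counts) == length(stoich) &&
        setequal(names(counts), names(stoich)) &&
        all(counts[names(stoich)] == stoich)
    }
    if (!same_counts(parsed$forward$counts, reactants)) {
      stop("read_sbml: reaction ", rid,
           ": kinetic law is not mass action in the declared reactants")
    }
    rev_rate <- NULL
    if (!is.null(parsed$reverse)) {
      if (!same_counts(parsed$reverse$counts, products)) {
        stop("read_sbml: reaction ", rid,
             ": reverse term is not mass action in the declared products")
      }
      rev_rate <- parsed$reverse$const
    }
    reactions[[length(reactions) + 1]] <- list(
      id = rid, reactants = reactants, products = products,
      rate = parsed$forward$const, reverse_rate = rev_rate)
  }
  kinetic_model(species, reactions)
}

# parse a MathML node into {const, species exponent counts}; supports
# ci / cn / times / power, and a top-level binary minus for reversibility
parse_mass_action <- function(node, species_names, consts, rid) {
  product_of <- function(nd) {
    nm <- xml2::xml_name(nd)
    if (nm == "ci") {
      sym <- trimws(xml2::xml_text(nd))
      if (sym %in% species_names) {
        return(list(const = 1, counts = stats::setNames(1L, sym)))
      }
      if (!is.null(consts[[sym]])) {
        return(list(const = consts[[sym]], counts = stats::setNames(integer(0), character(0))))
      }
      stop("read_sbml: reaction ", rid, ": unknown symbol '", sym, "'")
    }
    if (nm == "cn") {
      return(list(const = as.numeric(xml2::xml_text(nd)),
                  counts = stats::setNames(integer(0), character(0))))
    }
    if (nm == "apply") {
      ch <- xml2::xml_children(nd)
      op <- xml2::xml_name(ch[[1]])
      if (op == "times") {
        out <- list(const = 1, counts = stats::setNames(integer(0), character(0)))
        for (i in 2:length(ch)) {
          part <- product_of(ch[[i]])
          out$const <- out$const * part$const
          for (s in names(part$counts)) {
            out$counts[s] <- (if (s %in% names(out$counts)) out$counts[[s]] else 0L) +
              part$counts[[s]]
          }
        }
        return(out)
      }
      if (op == "power") {
        base <- product_of(ch[[2]])
        expn <- as.numeric(xml2::xml_text(ch[[3]]))
        if (length(base$counts) != 1 || expn != round(expn) || expn < 1) {
          stop("read_sbml: reaction ", rid, ": unsupported power term")
        }
        base$counts[1] <- base$counts[[1]] * as.integer(expn)
        return(base)
      }
      stop("read_sbml: reaction ", rid, ": unsupported operator '", op,
           "' (only mass-action rate laws are supported)")
    }
    stop("read_sbml: reaction ", rid, ": unsupported math element '", nm, "'")
  }
  nm <- xml2::xml_name(node)
  if (nm == "apply" &&
      xml2::xml_name(xml2::xml_children(node)[[1]]) == "minus") {
    ch <- xml2::xml_children(node)
    if (length(ch) != 3) {
      stop("read_sbml: reaction ", rid, ": unsupported difference form")
    }
    return(list(forward = product_of(ch[[2]]), reverse = product_of(ch[[3]])))
  }
  list(forward = product_of(node), reverse = NULL)
}

#' Write a kinetic model as SBML level 2
#'
#' Emits the same mass-action dialect [read_sbml()] consumes, so
#' write-then-load round trips are exact.
#'
#' @param model a [kinetic_model].
#' @param path output file path.
#' @param model_id model identifier attribute.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path, model_id = "model") {
  stopifnot(inherits(model, "kinetic_model"))
  num <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">',
    sprintf('  <model id="%s">', model_id),
    '    <listOfCompartments>',
    '      <compartment id="cell" size="1"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  for (sp in names(model$species)) {
    lines <- c(lines, sprintf(
      '      <species id="%s" compartment="cell" initialConcentration="%s"/>',
      sp, num(model$species[[sp]])))
  }
  lines <- c(lines, '    </listOfSpecies>', '    <listOfReactions>')
  math_product <- function(k_name, stoich) {
    cis <- c(sprintf("<ci> %s </ci>", k_name),
             unlist(lapply(names(stoich), function(s)
               rep(sprintf("<ci> %s </ci>", s), stoich[[s]]))))
    if (length(cis) == 1) cis[1] else
      paste0("<apply><times/>", paste(cis, collapse = ""), "</apply>")
  }
  for (r in model$reactions) {
    rev <- !is.null(r$reverse_rate)
    lines <- c(lines, sprintf('      <reaction id="%s" reversible="%s">',
                              r$id, if (rev) "true" else "false"))
    refs <- function(tag, stoich) {
      if (!length(stoich)) return(character(0))
      c(sprintf('        <listOf%s>', tag),
        sprintf('          <speciesReference species="%s" stoichiometry="%d"/>',
                names(stoich), as.integer(stoich)),
        sprintf('        </listOf%s>', tag))
    }
    lines <- c(lines, refs("Reactants", r$reactants), refs("Products", r$products))
    fwd <- math_product("kf", r$reactants)
    math <- if (rev) {
      paste0("<apply><minus/>", fwd, math_product("kr", r$products), "</apply>")
    } else fwd
    lines <- c(lines,
      '        <kineticLaw>',
      '          <math xmlns="http://www.w3.org/1998/Math/MathML">',
      paste0('            ', math),
      '          </math>',
      '          <listOfParameters>',
      sprintf('            <parameter id="kf" value="%s"/>', num(r$rate)),
      if (rev) sprintf('            <parameter id="kr" value="%s"/>',
                       num(r$reverse_rate)),
      '          </listOfParameters>',
      '        </kineticLaw>',
      '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>', '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}
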