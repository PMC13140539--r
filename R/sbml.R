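# Minimal SBML Level 3 reader/writer for stoichiometric models.
# Reads species (id, compartment, boundaryCondition), reactions (reactant and
# product stoichiometry, reversible flag). Kinetic laws, rules and fbc
# extensions are ignored; bounds come from the YAML config.

read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in SBML file: ", path)

  sp_nodes <- xml2::xml_find_all(model, ".//listOfSpecies/species")
  species <- lapply(sp_nodes, function(nd) {
    list(id = xml2::xml_attr(nd, "id"),
         compartment = xml2::xml_attr(nd, "compartment"),
         boundary = identical(xml2::xml_attr(nd, "boundaryCondition"), "true"))
  })
  if (anyDuplicated(vapply(species, `[[`, "", "id"))) {
    stop("duplicate species ids in SBML file")
  }

  rx_nodes <- xml2::xml_find_all(model, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(nd) {
    refs <- function(xp, sign) {
      refnodes <- xml2::xml_find_all(nd, xp)
      st <- vapply(refnodes, function(r) {
        s <- xml2::xml_attr(r, "stoichiometry")
        if (is.na(s)) 1 else as.numeric(s)
      }, numeric(1))
      setNames(sign * st, vapply(refnodes, xml2::xml_attr, "", "species"))
    }
    stoich <- c(refs(".//listOfReactants/speciesReference", -1),
                refs(".//listOfProducts/speciesReference", +1))
    # a species on both sides nets out
    stoich <- tapply(stoich, names(stoich), sum)
    stoich <- setNames(as.numeric(stoich), names(stoich))
    list(id = xml2::xml_attr(nd, "id"),
         stoich = stoich[stoich != 0],
         reversible = identical(xml2::xml_attr(nd, "reversible"), "true"))
  })
  list(species = species, reactions = reactions)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Write a network's stoichiometry as SBML Level 3
#'
#' Emits species (with compartment and boundary flags) and reactions
#' (reactants/products/reversibility). Atom transitions and bounds are not
#' representable in plain SBML core and are written by [write_atommap()] and
#' the YAML config instead.
#'
#' @param network a [reaction_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(network, path) {
  comps <- unique(vapply(network$metabolites, `[[`, "", "compartment"))
  ln <- c('<?xml version="1.0" encoding="UTF-8"?>',
          '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">',
          '  <model id="model">',
          '    <listOfCompartments>')
  for (cp in comps) {
    ln <- c(ln, sprintf('      <compartment id="%s" constant="true"/>',
                        xml_escape(gsub("[^A-Za-z0-9_]", "_", cp))))
  }
  ln <- c(ln, "    </listOfCompartments>", "    <listOfSpecies>")
  for (m in network$metabolites) {
    ln <- c(ln, sprintf(
      '      <species id="%s" compartment="%s" boundaryCondition="%s" hasOnlySubstanceUnits="false" constant="false"/>',
      xml_escape(m$id), xml_escape(gsub("[^A-Za-z0-9_]", "_", m$compartment)),
      if (m$is_boundary) "true" else "false"))
  }
  ln <- c(ln, "    </listOfSpecies>", "    <listOfReactions>")
  for (rx in network$reactions) {
    ln <- c(ln, sprintf('      <reaction id="%s" reversible="%s">',
                        xml_escape(rx$id), if (rx$reversible) "true" else "false"))
    subs <- rx$stoich[rx$stoich < 0]
    prods <- rx$stoich[rx$stoich > 0]
    if (length(subs)) {
      ln <- c(ln, "        <listOfReactants>")
      for (i in seq_along(subs)) {
        ln <- c(ln, sprintf('          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
                            xml_escape(names(subs)[i]), -subs[i]))
      }
      ln <- c(ln, "        </listOfReactants>")
    }
    if (length(prods)) {
      ln <- c(ln, "        <listOfProducts>")
      for (i in seq_along(prods)) {
        ln <- c(ln, sprintf('          <speciesReference species="%s" stoichiometry="%g" constant="true"/>',
                            xml_escape(names(prods)[i]), prods[i]))
      }
      ln <- c(ln, "        </listOfProducts>")
    }
    ln <- c(ln, "      </reaction>")
  }
  ln <- c(ln, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(ln, path)
  invisible(path)
}
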