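# SBML import (levels 1-3, standard or COBRA dialect) and level-2 export.
#
# Parsing is namespace-stripped, so one code path covers all level
# namespaces; the level-1 "specie" element spelling is accepted.  Import
# has two modes: "strict" fails on any deviation from the standard, and
# "lax" applies the common COBRA-world repairs, each recorded with a
# warning in the import report:
#   (a) decimal stoichiometry at levels that only allow integers
#   (b) boundary species marked by an id suffix ("_b") instead of the
#       boundaryCondition attribute: an exchange reaction is auto-created
#   (c) species referenced in reactions but never defined: dropped
#   (d) irreversible reactions with a negative LOWER_BOUND: the COBRA
#       bounds win, the reversibility conflict is recorded

sbml_boundary_suffix <- "_b"

new_report <- function() {
  list(warnings = data.frame(code = character(0), message = character(0),
                             location = character(0),
                             stringsAsFactors = FALSE),
       repairs = character(0))
}

report_add <- function(report, code, message, location, repair = FALSE) {
  report$warnings <- rbind(report$warnings,
                           data.frame(code = code, message = message,
                                      location = location,
                                      stringsAsFactors = FALSE))
  if (repair) report$repairs <- c(report$repairs, code)
  report
}

# strip "M_"/"R_" prefixes and a trailing compartment token matching the
# declared compartment; the original id is kept for traceability
decode_species_id <- function(id, compartment) {
  base <- sub("^M_", "", id)
  cmpt <- compartment %||% ""
  if (!nzchar(cmpt)) {
    m <- regmatches(base, regexec("^(.*)_([a-z0-9]{1,2})$", base))[[1]]
    if (length(m)) {
      base <- m[2]
      cmpt <- m[3]
    }
  } else if (grepl(paste0("_", cmpt, "$"), base)) {
    base <- sub(paste0("_", cmpt, "$"), "", base)
  }
  list(base = base, compartment = cmpt)
}

xml_attr_or <- function(node, attr, default = NULL) {
  v <- xml2::xml_attr(node, attr)
  if (is.na(v)) default else v
}

#' Import a model from SBML
#'
#' @param path Path to an SBML file (level 1, 2 or 3).
#' @param mode `"lax"` (apply COBRA-dialect repairs, with warnings) or
#'   `"strict"` (any deviation is an error).
#' @return A list with elements `model` (a [gem_model()]) and `report`
#'   (warnings and applied repairs).  In strict mode the report carries
#'   zero repairs.
#' @export
import_sbml <- function(path, mode = c("lax", "strict")) {
  mode <- match.arg(mode)
  strict <- mode == "strict"
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) gem_stop("malformed XML in '", path,
                                               "': ", conditionMessage(e)))
  level <- as.integer(xml_attr_or(xml2::xml_root(doc), "level", "2"))
  xml2::xml_ns_strip(doc)
  report <- new_report()
  mnode <- xml2::xml_find_first(doc, ".//model")
  if (inherits(mnode, "xml_missing")) gem_stop("no <model> element in SBML")
  mname <- xml_attr_or(mnode, "name", xml_attr_or(mnode, "id", "model"))

  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  if (length(sp_nodes) == 0)
    sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/specie")
  compounds <- list()
  sp_info <- list()
  for (sp in sp_nodes) {
    sid <- xml_attr_or(sp, "id", xml_attr_or(sp, "name"))
    cmpt <- xml_attr_or(sp, "compartment")
    boundary <- identical(xml_attr_or(sp, "boundaryCondition"), "true")
    dec <- decode_species_id(sid, cmpt)
    suffix_boundary <- grepl(paste0(sbml_boundary_suffix, "$"), sid) &&
      !boundary
    if (suffix_boundary) {
      if (strict)
        gem_stop("species '", sid, "' uses the boundary id suffix '",
                 sbml_boundary_suffix, "' instead of boundaryCondition ",
                 "(strict mode)")
      report <- report_add(report, "boundary_suffix",
                           paste0("species '", sid, "' treated as boundary",
                                  " compound; exchange reaction created"),
                           sid, repair = TRUE)
    }
    charge <- xml_attr_or(sp, "charge")
    key <- compound_key(dec$base, dec$compartment)
    sp_info[[sid]] <- list(base = dec$base, compartment = dec$compartment,
                           boundary = boundary,
                           suffix_boundary = suffix_boundary, key = key)
    if (!dec$base %in% names(compounds))
      compounds[[dec$base]] <- compound_entry(
        dec$base, name = xml_attr_or(sp, "name"),
        charge = if (!is.null(charge)) as.integer(charge),
        boundary = boundary,
        extra = list(sbml_id = sid))
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- list()
  limits <- list()
  objectives <- numeric(0)
  for (rx in rx_nodes) {
    rid_raw <- xml_attr_or(rx, "id", xml_attr_or(rx, "name"))
    rid <- sub("^R_", "", rid_raw)
    reversible <- !identical(xml_attr_or(rx, "reversible", "true"), "false")
    read_side <- function(xpath) {
      refs <- xml2::xml_find_all(rx, xpath)
      rows <- list()
      for (ref in refs) {
        sid <- xml_attr_or(ref, "species", xml_attr_or(ref, "specie"))
        st_txt <- xml_attr_or(ref, "stoichiometry", "1")
        st <- as.numeric(st_txt)
        if (level == 1 && st != round(st)) {
          if (strict)
            gem_stop("decimal stoichiometry ", st_txt, " in reaction '",
                     rid_raw, "' is not allowed in level-1 SBML ",
                     "(strict mode)")
          report <<- report_add(report, "decimal_stoichiometry",
                                paste0("decimal stoichiometry ", st_txt,
                                       " accepted in level-1 reaction '",
                                       rid_raw, "'"),
                                rid_raw, repair = TRUE)
        }
        info <- sp_info[[sid]]
        if (is.null(info)) {
          if (strict)
            gem_stop("reaction '", rid_raw, "' references undefined ",
                     "species '", sid, "' (strict mode)")
          report <<- report_add(report, "undefined_species",
                                paste0("undefined species '", sid,
                                       "' removed from reaction '",
                                       rid_raw, "'"),
                                rid_raw, repair = TRUE)
          next
        }
        rows[[length(rows) + 1L]] <- eq_side(info$base, info$compartment, st)
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    }
    left <- read_side(".//listOfReactants/speciesReference|.//listOfReactants/specieReference")
    right <- read_side(".//listOfProducts/speciesReference|.//listOfProducts/specieReference")
    params <- xml2::xml_find_all(rx, ".//kineticLaw//parameter|.//kineticLaw//localParameter")
    lower <- upper <- objc <- NULL
    for (pm in params) {
      pid <- xml_attr_or(pm, "id", xml_attr_or(pm, "name", ""))
      val <- as.numeric(xml_attr_or(pm, "value", "NA"))
      if (pid == "LOWER_BOUND") lower <- val
      if (pid == "UPPER_BOUND") upper <- val
      if (pid == "OBJECTIVE_COEFFICIENT") objc <- val
    }
    if (!reversible && !is.null(lower) && lower < 0) {
      if (strict)
        gem_stop("reaction '", rid_raw, "' is irreversible but has ",
                 "LOWER_BOUND = ", lower, " (strict mode)")
      report <- report_add(report, "reversibility_conflict",
                           paste0("irreversible reaction '", rid_raw,
                                  "' keeps its negative LOWER_BOUND ",
                                  lower),
                           rid_raw, repair = TRUE)
    }
    direction <- if (reversible) "both" else "forward"
    eq <- equation(left, right, direction = direction)
    reactions[[length(reactions) + 1L]] <-
      reaction_entry(rid, eq, extra = list(sbml_id = rid_raw))
    if (!is.null(lower) || !is.null(upper))
      limits[[length(limits) + 1L]] <-
        list(reaction = rid, lower = lower, upper = upper)
    if (!is.null(objc) && objc != 0) objectives[rid] <- objc
  }
  # auto-create exchange reactions for suffix-marked boundary species
  for (sid in names(sp_info)) {
    info <- sp_info[[sid]]
    if (!info$suffix_boundary) next
    ex_id <- paste0("EX_", info$base)
    if (ex_id %in% vapply(reactions, function(r) r$id, character(1))) next
    reactions[[length(reactions) + 1L]] <-
      reaction_entry(ex_id,
                     equation(eq_side(info$base, info$compartment), NULL,
                              "both"),
                     extra = list(sbml_id = ""))
  }
  model <- suppressWarnings(gem_model(
    name = mname, reactions = reactions, compounds = unname(compounds),
    limits = limits,
    default_flux_limit = 1000))
  bio <- detect_biomass(model, objectives)
  if (!is.null(bio)) {
    model <- suppressWarnings(gem_model(
      name = mname, reactions = unname(model$reactions),
      compounds = unname(model$compounds), biomass = bio,
      limits = limits, default_flux_limit = 1000))
  }
  attr(model, "objectives") <- objectives
  list(model = model, report = report)
}

#' Export a model to SBML (level 2, COBRA dialect)
#'
#' Writes level-2 SBML with COBRA-style kineticLaw parameters
#' (`LOWER_BOUND`, `UPPER_BOUND`, `OBJECTIVE_COEFFICIENT`; the biomass
#' reaction gets objective coefficient 1).  Boundary compounds are
#' exported with `boundaryCondition="true"`, never with an id suffix.
#' [import_sbml()] in strict mode reads the result back to an equivalent
#' model.
#'
#' @param model A [gem_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_sbml <- function(model, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s)
    s <- gsub("<", "&lt;", s)
    s <- gsub(">", "&gt;", s)
    gsub("\"", "&quot;", s)
  }
  sanitize <- function(s) gsub("[^A-Za-z0-9_]", "_", s)
  lines <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
             paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level2\" ",
                    "level=\"2\" version=\"1\">"),
             paste0("  <model id=\"", sanitize(model$name), "\" name=\"",
                    esc(model$name), "\">"))
  # compartments actually used
  cmpts <- unique(unlist(lapply(model$reactions, function(r)
    c(r$equation$left$compartment, r$equation$right$compartment))))
  cmpts <- cmpts[nzchar(cmpts)]
  lines <- c(lines, "    <listOfCompartments>",
             vapply(unique(c(cmpts, "cell")), function(cm)
               paste0("      <compartment id=\"", cm, "\"/>"),
               character(1)),
             "    </listOfCompartments>")
  # species: every (compound, compartment) pair used, plus bare entries
  pairs <- unique(do.call(rbind, c(list(data.frame(compound = character(0),
                                                   compartment = character(0))),
    lapply(model$reactions, function(r)
      rbind(r$equation$left[, c("compound", "compartment")],
            r$equation$right[, c("compound", "compartment")])))))
  sp_id <- function(base, cmpt)
    paste0("M_", sanitize(base), if (nzchar(cmpt)) paste0("_", cmpt))
  lines <- c(lines, "    <listOfSpecies>")
  for (i in seq_len(nrow(pairs))) {
    base <- pairs$compound[i]
    cmpt <- pairs$compartment[i]
    cp <- model$compounds[[base]]
    attrs <- paste0("id=\"", sp_id(base, cmpt), "\" name=\"", esc(base),
                    "\" compartment=\"",
                    if (nzchar(cmpt)) cmpt else "cell", "\"")
    if (!is.null(cp) && !is.null(cp$charge))
      attrs <- paste0(attrs, " charge=\"", cp$charge, "\"")
    if (!is.null(cp) && isTRUE(cp$boundary))
      attrs <- paste0(attrs, " boundaryCondition=\"true\"")
    lines <- c(lines, paste0("      <species ", attrs, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>", "    <listOfReactions>")
  for (rid in names(model$reactions)) {
    r <- model$reactions[[rid]]
    eq <- normalize_equation(r$equation)
    bb <- model_bounds(model, rid)
    reversible <- eq$direction == "both" || bb[1] < 0
    lines <- c(lines, paste0("      <reaction id=\"R_", sanitize(rid),
                             "\" name=\"", esc(r$name %||% rid),
                             "\" reversible=\"",
                             if (reversible) "true" else "false", "\">"))
    side_xml <- function(side, tag) {
      if (nrow(side) == 0) return(character(0))
      c(paste0("        <", tag, ">"),
        vapply(seq_len(nrow(side)), function(i)
          paste0("          <speciesReference species=\"",
                 sp_id(side$compound[i], side$compartment[i]),
                 "\" stoichiometry=\"", num_fmt(side$coef[i]), "\"/>"),
          character(1)),
        paste0("        </", tag, ">"))
    }
    lines <- c(lines, side_xml(eq$left, "listOfReactants"),
               side_xml(eq$right, "listOfProducts"))
    objc <- if (identical(model$biomass, rid)) 1 else 0
    lines <- c(lines,
               "        <kineticLaw>",
               "          <math xmlns=\"http://www.w3.org/1998/Math/MathML\"><ci> FLUX_VALUE </ci></math>",
               "          <listOfParameters>",
               paste0("            <parameter id=\"LOWER_BOUND\" value=\"",
                      num_fmt(bb[1]), "\"/>"),
               paste0("            <parameter id=\"UPPER_BOUND\" value=\"",
                      num_fmt(bb[2]), "\"/>"),
               paste0("            <parameter id=\"OBJECTIVE_COEFFICIENT\"",
                      " value=\"", objc, "\"/>"),
               "          </listOfParameters>",
               "        </kineticLaw>",
               "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
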