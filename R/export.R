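#' Export a network to SBML or a plain-text reaction listing
#'
#' The text format writes one reaction per line,
#' `A + B + C -> A' + B + C ; k=1 ; subnet=R2alpha` (transformed species
#' first, catalysts repeated on both sides), preceded by a header recording
#' the network dimensions; [import_network()] round-trips it. The SBML
#' output is a level-3 version-2 document with every species (initial
#' amounts taken from `state` when given) and one reaction per line of the
#' table, catalysts as `modifierSpeciesReference`s and a mass-action
#' `kineticLaw`.
#'
#' @param crn A [build_bw_network()] object.
#' @param path Output file path.
#' @param format `"text"` or `"sbml"`.
#' @param state Optional named concentration vector used for initial amounts
#'   (SBML) or recorded as comments (text).
#' @return `path`, invisibly.
#' @export
export_network <- function(crn, path, format = c("text", "sbml"), state = NULL) {
  format <- match.arg(format)
  if (format == "text") export_network_text(crn, path, state)
  else export_network_sbml(crn, path, state)
  invisible(path)
}

export_network_text <- function(crn, path, state = NULL) {
  nm <- crn$species$name
  hdr <- sprintf(
    "#! bwcrn n_hidden=%d n_visible=%d seq_lengths=%s h_star=%d v_star=%d learn_pi=%s",
    crn$n_hidden, crn$n_visible, paste(crn$seq_lengths, collapse = ","),
    crn$h_star, crn$v_star, crn$learn_pi)
  lines <- vapply(seq_len(nrow(crn$reactions)), function(j) {
    rx <- crn$reactions[j, ]
    cats <- nm[rx$catalysts[[1]]]
    lhs <- paste(c(nm[rx$from], cats), collapse = " + ")
    rhs <- paste(c(nm[rx$to], cats), collapse = " + ")
    sprintf("%s -> %s ; k=%g ; subnet=%s", lhs, rhs, rx$rate, rx$subnetwork)
  }, character(1))
  out <- c(hdr, lines)
  if (!is.null(state))
    out <- c(out, "", paste0("# init ", nm, " = ", format(state, digits = 15)))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(out, con)
}

#' Re-import a plain-text network listing
#'
#' @param path A file written by [export_network()] with `format = "text"`.
#' @return A `"bw_crn"` object identical to the exported one.
#' @export
import_network <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  if (!startsWith(hdr, "#! bwcrn"))
    stop("not a bwcrn network file (missing header): ", path, call. = FALSE)
  get_field <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", hdr)
  n_hidden <- as.integer(get_field("n_hidden"))
  n_visible <- as.integer(get_field("n_visible"))
  seq_lengths <- as.integer(strsplit(get_field("seq_lengths"), ",")[[1]])
  learn_pi <- as.logical(get_field("learn_pi"))
  species <- enumerate_species(n_hidden, n_visible, seq_lengths, learn_pi)
  id_map <- stats::setNames(species$id, species$name)
  rx_lines <- lines[-1]
  rx_lines <- rx_lines[nzchar(rx_lines) & !startsWith(rx_lines, "#")]
  parsed <- lapply(rx_lines, function(ln) {
    parts <- strsplit(ln, "\\s*;\\s*")[[1]]
    sides <- strsplit(parts[1], "\\s*->\\s*")[[1]]
    lhs <- strsplit(sides[1], "\\s*\\+\\s*")[[1]]
    rhs <- strsplit(sides[2], "\\s*\\+\\s*")[[1]]
    from <- id_map[[lhs[1]]]; to <- id_map[[rhs[1]]]
    if (is.null(from) || is.null(to))
      stop("unknown species in: ", ln, call. = FALSE)
    cats <- unname(id_map[lhs[-1]])
    if (anyNA(cats)) stop("unknown catalyst in: ", ln, call. = FALSE)
    if (!identical(sort(lhs[-1]), sort(rhs[-1])))
      stop("catalysts differ across sides in: ", ln, call. = FALSE)
    k <- as.numeric(sub("k=", "", parts[2]))
    list(from = from, to = to, cats = as.integer(cats), rate = k,
         subnet = sub("subnet=", "", parts[3]))
  })
  sub_lab <- vapply(parsed, `[[`, character(1), "subnet")
  part <- sub("^(s[0-9]+:)?R[0-9]*", "", sub_lab)
  lnum <- suppressWarnings(as.integer(sub("^(s[0-9]+:)?R([0-9]+).*", "\\2", sub_lab)))
  inum <- suppressWarnings(as.integer(sub("^s([0-9]+):.*", "\\1", sub_lab)))
  if (length(seq_lengths) == 1) inum[!part %in% c("theta", "psi", "pi")] <- 1L
  reactions <- tibble::tibble(
    from = vapply(parsed, `[[`, integer(1), "from"),
    to = vapply(parsed, `[[`, integer(1), "to"),
    catalysts = lapply(parsed, `[[`, "cats"),
    rate = vapply(parsed, `[[`, numeric(1), "rate"),
    part = part, l = lnum, i = inum, subnetwork = sub_lab)
  structure(list(species = species, reactions = reactions,
                 n_hidden = n_hidden, n_visible = n_visible,
                 seq_lengths = seq_lengths,
                 h_star = as.integer(get_field("h_star")),
                 v_star = as.integer(get_field("v_star")),
                 learn_pi = learn_pi),
            class = "bw_crn")
}

export_network_sbml <- function(crn, path, state = NULL) {
  doc <- xml2::xml_new_root(
    "sbml", xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2")
  model <- xml2::xml_add_child(doc, "model", id = "bw_reaction_network")
  lc <- xml2::xml_add_child(model, "listOfCompartments")
  xml2::xml_add_child(lc, "compartment", id = "cell", constant = "true",
                      spatialDimensions = "3", size = "1")
  ls <- xml2::xml_add_child(model, "listOfSpecies")
  for (k in seq_len(nrow(crn$species))) {
    amt <- if (is.null(state)) 0 else unname(state[k])
    xml2::xml_add_child(ls, "species",
                        id = crn$species$name[k], compartment = "cell",
                        initialAmount = format(amt, digits = 15),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = if (crn$species$role[k] == "E")
                          "true" else "false",
                        constant = "false")
  }
  lr <- xml2::xml_add_child(model, "listOfReactions")
  nm <- crn$species$name
  for (j in seq_len(nrow(crn$reactions))) {
    rx <- crn$reactions[j, ]
    rnode <- xml2::xml_add_child(lr, "reaction", id = sprintf("r%d", j),
                                 reversible = "false")
    lre <- xml2::xml_add_child(rnode, "listOfReactants")
    xml2::xml_add_child(lre, "speciesReference", species = nm[rx$from],
                        stoichiometry = "1", constant = "true")
    lpr <- xml2::xml_add_child(rnode, "listOfProducts")
    xml2::xml_add_child(lpr, "speciesReference", species = nm[rx$to],
                        stoichiometry = "1", constant = "true")
    cats <- rx$catalysts[[1]]
    if (length(cats)) {
      lmo <- xml2::xml_add_child(rnode, "listOfModifiers")
      for (cc in cats)
        xml2::xml_add_child(lmo, "modifierSpeciesReference", species = nm[cc])
    }
    kl <- xml2::xml_add_child(rnode, "kineticLaw")
    math <- xml2::xml_add_child(kl, "math",
                                xmlns = "http://www.w3.org/1998/Math/MathML")
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "times")
    xml2::xml_add_child(ap, "cn", format(rx$rate, digits = 15))
    for (s in c(rx$from, cats)) xml2::xml_add_child(ap, "ci", nm[s])
  }
  xml2::write_xml(doc, path)
}
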