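# Model input/output: a plain-text native dialect (write + read,
# round-trip exact) and a reader for the SBML Level 3 + FBC subset that
# genome-scale constraint-based models use (species, reactions, fbc
# bounds, fbc objective, fbc gene-product associations).

#' Write a model in the native plain-text dialect
#'
#' The dialect is line-oriented:
#' \preformatted{
#' # kivflux native model v1
#' MODEL <name>
#' COMPARTMENTS <tag> <tag> ...
#' OBJECTIVE <reaction id>
#' METABOLITE <id> <compartment> "<display name>"
#' REACTION <id> : 2 pyr_c --> 1 alac_c [0, 1000] GPR "alsS" EXCHANGE
#' }
#' Each reaction line holds the signed stoichiometry split across an
#' arrow (`-->` irreversible, `<=>` reversible), an optional
#' `[lb, ub]` bounds pair (defaults `[0, 1000]` and `[-1000, 1000]`
#' respectively when omitted), an optional quoted GPR rule and an
#' optional `EXCHANGE` flag.  Bounds are written at full precision so a
#' write/read round trip reproduces the model exactly.
#'
#' @param model A [metabolic_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_native_model <- function(model, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    "# kivflux native model v1",
    paste("MODEL", model$name),
    paste("COMPARTMENTS", paste(model$compartments, collapse = " ")),
    paste("OBJECTIVE", model$objective_id)
  )
  lines <- c(lines, purrr::pmap_chr(model$metabolites, function(id, name,
                                                               compartment) {
    sprintf('METABOLITE %s %s "%s"', id, compartment, name)
  }))
  side_str <- function(st) {
    if (!length(st)) return("")
    paste(sprintf("%s %s", num(abs(unname(st))), names(st)), collapse = " + ")
  }
  lines <- c(lines, purrr::pmap_chr(
    model$reactions,
    function(id, name, stoichiometry, lb, ub, gene_rule, is_exchange) {
      st <- stoichiometry
      lhs <- side_str(st[st < 0])
      rhs <- side_str(st[st > 0])
      arrow <- if (lb < 0) "<=>" else "-->"
      idpart <- if (identical(name, id)) id else sprintf('%s "%s"', id, name)
      line <- sprintf("REACTION %s : %s %s %s [%s, %s]", idpart, lhs, arrow,
                      rhs, num(lb), num(ub))
      if (nzchar(gene_rule)) line <- sprintf('%s GPR "%s"', line, gene_rule)
      if (isTRUE(is_exchange)) line <- paste(line, "EXCHANGE")
      gsub("  +", " ", line)
    }
  ))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model from the native plain-text dialect
#'
#' Parses the format documented in [write_native_model()].  Syntax errors
#' are reported with their line number.  Reactions keep file order (the
#' stoichiometric matrix column order derives from it).
#'
#' @param path Input file path.
#' @return A [metabolic_model()].
#' @export
read_native_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  bail <- function(i, msg) {
    stop(sprintf("%s:%d: %s", basename(path), i, msg), call. = FALSE)
  }
  model_name <- "model"
  compartments <- NULL
  objective <- NULL
  mets <- list()
  rxns <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line) || startsWith(line, "#")) next
    kw <- sub("\\s.*$", "", line)
    rest <- trimws(sub("^\\S+\\s*", "", line))
    if (kw == "MODEL") {
      model_name <- rest
    } else if (kw == "COMPARTMENTS") {
      compartments <- strsplit(rest, "\\s+")[[1]]
    } else if (kw == "OBJECTIVE") {
      objective <- rest
    } else if (kw == "METABOLITE") {
      m <- regmatches(rest,
                      regexec('^(\\S+)\\s+(\\S+)(?:\\s+"(.*)")?\\s*$', rest))[[1]]
      if (!length(m)) bail(i, "malformed METABOLITE line")
      mets[[length(mets) + 1L]] <- tibble::tibble(
        id = m[2], name = if (nzchar(m[4])) m[4] else m[2],
        compartment = m[3])
    } else if (kw == "REACTION") {
      rxns[[length(rxns) + 1L]] <- parse_native_reaction(rest, i, bail)
    } else {
      bail(i, paste0("unknown directive '", kw, "'"))
    }
  }
  if (!length(rxns)) stop("no reactions in ", path, call. = FALSE)
  if (is.null(objective)) stop("no OBJECTIVE in ", path, call. = FALSE)
  if (is.null(compartments)) compartments <- unique(
    purrr::map_chr(mets, "compartment"))
  metabolic_model(dplyr::bind_rows(mets), dplyr::bind_rows(rxns),
                  objective_id = objective, compartments = compartments,
                  name = model_name)
}

parse_native_reaction <- function(rest, i, bail) {
  m <- regexec("^(\\S+)\\s*(?:\"([^\"]*)\")?\\s*:\\s*(.*)$", rest)
  m <- regmatches(rest, m)[[1]]
  if (!length(m)) bail(i, "malformed REACTION line (missing 'id :')")
  id <- m[2]
  rxn_name <- if (nzchar(m[3])) m[3] else id
  body <- m[4]
  is_exchange <- grepl("\\sEXCHANGE\\s*$", paste0(" ", body))
  body <- sub("\\s*EXCHANGE\\s*$", "", body)
  gene_rule <- ""
  gm <- regmatches(body, regexec('\\sGPR\\s+"([^"]*)"\\s*$', body))[[1]]
  if (length(gm)) {
    gene_rule <- gm[2]
    body <- sub('\\s*GPR\\s+"[^"]*"\\s*$', "", body)
  }
  lb <- NA_real_
  ub <- NA_real_
  bm <- regmatches(body,
                   regexec("\\[\\s*([^],]+)\\s*,\\s*([^]]+)\\s*\\]\\s*$",
                           body))[[1]]
  if (length(bm)) {
    lb <- suppressWarnings(as.numeric(trimws(bm[2])))
    ub <- suppressWarnings(as.numeric(trimws(bm[3])))
    if (is.na(lb) || is.na(ub)) bail(i, "non-numeric bounds")
    body <- sub("\\[[^]]*\\]\\s*$", "", body)
  }
  arrow <- if (grepl("<=>", body, fixed = TRUE)) "<=>"
           else if (grepl("-->", body, fixed = TRUE)) "-->"
           else bail(i, "missing reaction arrow ('-->' or '<=>')")
  if (is.na(lb)) {                      # stated dialect defaults
    lb <- if (arrow == "<=>") -1000 else 0
    ub <- 1000
  }
  if (lb > ub) bail(i, sprintf("lower bound %g exceeds upper bound %g", lb, ub))
  sides <- strsplit(body, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2L) bail(i, "more than one reaction arrow")
  if (length(sides) == 1L) sides <- c(sides, "")
  parse_side <- function(txt, sign) {
    txt <- trimws(txt)
    if (!nzchar(txt)) return(numeric())
    terms <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
    out <- purrr::map(terms, function(term) {
      if (!nzchar(term)) bail(i, "empty stoichiometric term")
      parts <- strsplit(term, "\\s+")[[1]]
      if (length(parts) == 1L) {
        coeff <- 1
        met <- parts[1]
      } else if (length(parts) == 2L) {
        coeff <- suppressWarnings(as.numeric(parts[1]))
        if (is.na(coeff)) bail(i, paste0("bad coefficient in '", term, "'"))
        met <- parts[2]
      } else {
        bail(i, paste0("malformed term '", term, "'"))
      }
      stats::setNames(sign * coeff, met)
    })
    unlist(out)
  }
  st <- c(parse_side(sides[1], -1), parse_side(sides[2], 1))
  if (anyDuplicated(names(st))) {
    st <- tapply(st, names(st), sum)[unique(names(st))]
  }
  tibble::tibble(id = id, name = rxn_name, stoichiometry = list(st),
                 lb = lb, ub = ub, gene_rule = gene_rule,
                 is_exchange = is_exchange)
}

`%||NA%` <- function(a, b) if (is.na(a)) b else a

#' Read a constraint-based model from SBML Level 3 + FBC
#'
#' Parses the SBML-FBC subset genome-scale constraint-based models use:
#' compartments, species, reactions with stoichiometry, flux bounds
#' referenced through `fbc:lowerFluxBound`/`fbc:upperFluxBound`
#' parameters, the active FBC objective, and `fbc:geneProductAssociation`
#' trees (rendered to the package's GPR strings).  Boundary-condition
#' species are excluded from the network, as is conventional.  Other SBML
#' Level 3 packages flagged `required` are rejected with a clear message.
#' Infinite bound values are replaced by the community-conventional
#' ±1000 so the flux LP stays bounded.
#'
#' @param path Path to an SBML `.xml` file (Level 3, FBC package).
#' @return A [metabolic_model()].
#' @export
read_sbml_fbc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  root <- xml2::xml_find_first(doc, "/*[local-name()='sbml']")
  if (inherits(root, "xml_missing")) {
    stop("not an SBML document: ", path, call. = FALSE)
  }
  if (!identical(xml2::xml_attr(root, "level"), "3")) {
    stop("only SBML Level 3 is supported (file declares level ",
         xml2::xml_attr(root, "level"), ")", call. = FALSE)
  }
  attrs <- xml2::xml_attrs(root, ns = xml2::xml_ns(doc))
  req <- attrs[grepl(":required$", names(attrs)) & attrs == "true"]
  other <- setdiff(sub(":required$", "", names(req)), "fbc")
  if (length(other)) {
    stop("unsupported required SBML package(s): ",
         paste(other, collapse = ", "),
         "; only the FBC subset is handled", call. = FALSE)
  }
  if (!any(grepl("fbc", names(xml2::xml_ns(doc))) |
           grepl("/fbc/", unlist(xml2::xml_ns(doc))))) {
    stop("SBML file lacks the FBC package (no flux bounds/objective): ",
         path, call. = FALSE)
  }
  find_all <- function(node, what) {
    xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", what))
  }
  a <- function(node, name) xml2::xml_attr(node, name)
  fbc_attr <- function(node, name) {
    v <- xml2::xml_attr(node, paste0("fbc:", name))
    if (is.na(v)) v <- xml2::xml_attr(node, name)
    v
  }

  comp_nodes <- find_all(doc, "compartment")
  compartments <- xml2::xml_attr(comp_nodes, "id")

  params <- find_all(doc, "parameter")
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))

  sp_nodes <- find_all(doc, "species")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  dup <- unique(sp_id[duplicated(sp_id)])
  if (length(dup)) {
    stop("duplicate species id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  mets <- tibble::tibble(
    id = sp_id,
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), sp_id),
    compartment = xml2::xml_attr(sp_nodes, "compartment")
  )[!sp_boundary, ]
  boundary_ids <- sp_id[sp_boundary]

  gp_nodes <- find_all(doc, "geneProduct")
  gp_id <- purrr::map_chr(gp_nodes, fbc_attr, "id")
  gp_label <- purrr::map_chr(gp_nodes, fbc_attr, "label")
  gene_name <- stats::setNames(
    ifelse(is.na(gp_label) | !nzchar(gp_label), gp_id, gp_label), gp_id)

  gpr_string <- function(node) {
    ln <- xml2::xml_name(node)          # local name, prefix stripped
    if (ln == "geneProductRef") {
      ref <- fbc_attr(node, "geneProduct")
      g <- gene_name[ref]
      if (is.na(g)) g <- ref
      return(unname(g))
    }
    kids <- xml2::xml_children(node)
    parts <- purrr::map_chr(kids, gpr_string)
    if (ln == "and") paste0("(", paste(parts, collapse = " and "), ")")
    else if (ln == "or") paste0("(", paste(parts, collapse = " or "), ")")
    else if (length(parts) == 1L) parts
    else stop("unparsable gene association element '", ln, "'",
              call. = FALSE)
  }

  rx_nodes <- xml2::xml_find_all(
    doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rx_id <- xml2::xml_attr(rx_nodes, "id")
  dup <- unique(rx_id[duplicated(rx_id)])
  if (length(dup)) {
    stop("duplicate reaction id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rxns <- purrr::map(seq_along(rx_nodes), function(k) {
    node <- rx_nodes[[k]]
    rid <- rx_id[k]
    bound_of <- function(which) {
      ref <- fbc_attr(node, which)
      if (is.na(ref)) {
        stop("reaction '", rid, "' lacks fbc:", which, call. = FALSE)
      }
      val <- pvals[ref]
      if (is.na(val)) {
        stop("reaction '", rid, "' references undefined bound parameter '",
             ref, "'", call. = FALSE)
      }
      unname(val)
    }
    lb <- bound_of("lowerFluxBound")
    ub <- bound_of("upperFluxBound")
    # community convention: explicit infinities become +/-1000
    if (!is.finite(lb)) lb <- -1000
    if (!is.finite(ub)) ub <- 1000
    side <- function(tag, sign) {
      refs <- xml2::xml_find_all(node, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", tag))
      if (!length(refs)) return(numeric())
      sp <- xml2::xml_attr(refs, "species")
      coeff <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coeff[is.na(coeff)] <- 1
      keep <- !sp %in% boundary_ids
      stats::setNames(sign * coeff[keep], sp[keep])
    }
    st <- c(side("listOfReactants", -1), side("listOfProducts", 1))
    if (anyDuplicated(names(st))) {
      st <- tapply(st, names(st), sum)[unique(names(st))]
    }
    ga <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']/*")
    rule <- if (inherits(ga, "xml_missing")) "" else
      tryCatch(gpr_string(ga), error = function(e) {
        stop("reaction '", rid, "': ", conditionMessage(e), call. = FALSE)
      })
    tibble::tibble(
      id = rid, name = a(node, "name") %||NA% rid,
      stoichiometry = list(st), lb = lb, ub = ub, gene_rule = rule,
      is_exchange = length(st) <= 1L
    )
  })
  obj_node <- xml2::xml_find_first(doc, ".//*[local-name()='listOfObjectives']")
  if (inherits(obj_node, "xml_missing")) {
    stop("SBML file has no fbc objective", call. = FALSE)
  }
  active <- fbc_attr(obj_node, "activeObjective")
  fo <- xml2::xml_find_first(doc, sprintf(
    ".//*[local-name()='objective'][@*[local-name()='id']='%s']//*[local-name()='fluxObjective']",
    active))
  if (inherits(fo, "xml_missing")) {
    fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  }
  if (inherits(fo, "xml_missing")) {
    stop("SBML file defines no flux objective", call. = FALSE)
  }
  objective_id <- fbc_attr(fo, "reaction")

  model <- metabolic_model(
    mets, dplyr::bind_rows(rxns), objective_id = objective_id,
    compartments = compartments,
    name = a(xml2::xml_find_first(doc, ".//*[local-name()='model']"),
             "id") %||NA% basename(path)
  )
  # surface structural problems (duplicate/dangling ids) as parse errors
  findings <- validate_model(model)
  hard <- findings[findings$check %in%
                     c("duplicate_metabolite", "duplicate_reaction",
                       "unknown_metabolite", "missing_objective",
                       "bad_gene_rule", "bound_order"), ]
  if (nrow(hard)) {
    stop("invalid SBML model: ", paste(hard$message, collapse = "; "),
         call. = FALSE)
  }
  model
}
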