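#' Write and read a network as JSON
#'
#' The document records the scheme (variables with ordered states and
#' optional bin breaks), the target, and one node entry per variable
#' with its ordered parents and CPT rows.  Rows are ordered
#' lexicographically by declared parent order (first parent most
#' significant); within a row, child states follow their declared
#' order.  Probabilities are written at full precision, so write/read
#' round-trips are numerically exact.
#'
#' @param network a `"bn"` object.
#' @param path file path.
#' @return `read_network_json()` returns a `"bn"`;
#'   `write_network_json()` returns `path` invisibly.
#' @export
write_network_json <- function(network, path) {
  scheme <- network$scheme
  doc <- list(
    format = "sbsbn-network",
    version = 1L,
    target = scheme$target,
    variables = lapply(unname(scheme$variables), function(v) {
      out <- list(name = v$name, states = as.list(v$states))
      if (!is.null(v$breaks)) out$breaks <- v$breaks
      out
    }),
    nodes = lapply(network$structure$nodes, function(v) {
      list(name = v,
           parents = as.list(network$structure$parents[[v]]),
           cpt = apply(cpt_to_rows(network$cpts[[v]]), 1L, as.list,
                       simplify = FALSE))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  doc <- jsonlite::read_json(path)
  specs <- lapply(doc$variables, function(v)
    variable_spec(v$name, unlist(v$states),
                  breaks = if (!is.null(v$breaks)) unlist(v$breaks)))
  scheme <- variable_scheme(specs, target = doc$target)
  parents <- lapply(doc$nodes, function(nd) unlist(nd$parents) %||% character(0))
  names(parents) <- vapply(doc$nodes, `[[`, character(1), "name")
  st <- bn_structure(parents)
  cpts <- lapply(doc$nodes, function(nd) {
    rows <- do.call(rbind, lapply(nd$cpt, unlist))
    make_cpt(nd$name, unlist(nd$parents) %||% character(0), scheme,
             rows = rows)
  })
  names(cpts) <- names(parents)
  bn_network(scheme, st, cpts)
}

#' Write and read a variable scheme as YAML
#'
#' @param scheme a [variable_scheme()].
#' @param path file path.
#' @export
write_scheme_yaml <- function(scheme, path) {
  doc <- list(target = scheme$target,
              variables = lapply(unname(scheme$variables), function(v) {
                out <- list(name = v$name, states = as.list(v$states))
                if (!is.null(v$breaks))
                  out$breaks <- ifelse(is.finite(v$breaks), v$breaks,
                                       ".inf")
                out
              }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_scheme_yaml
#' @export
read_scheme_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  specs <- lapply(doc$variables, function(v) {
    br <- if (!is.null(v$breaks))
      as.numeric(ifelse(v$breaks == ".inf", Inf, v$breaks))
    variable_spec(v$name, unlist(v$states), breaks = br)
  })
  variable_scheme(specs, target = doc$target)
}

#' XMLBIF import and export
#'
#' Reads and writes networks in the XMLBIF 0.3 interchange format used
#' by common Bayesian-network tools.  `DEFINITION/TABLE` entries are
#' laid out with parent configurations in lexicographic order of the
#' `GIVEN` list (first parent most significant) and, within each
#' configuration, the child outcomes in declared order.  Discretization
#' bins are not representable in XMLBIF and are dropped on export.
#'
#' @param network a `"bn"` object.
#' @param path file path.
#' @param target outcome variable to record on import; defaults to
#'   `"HRUB"` when present, else the last variable.
#' @export
write_xmlbif <- function(network, path) {
  scheme <- network$scheme
  doc <- xml2::xml_new_root("BIF", VERSION = "0.3")
  nw <- xml2::xml_add_child(doc, "NETWORK")
  xml2::xml_add_child(nw, "NAME", "sbsbn")
  for (v in unname(scheme$variables)) {
    vn <- xml2::xml_add_child(nw, "VARIABLE", TYPE = "nature")
    xml2::xml_add_child(vn, "NAME", v$name)
    for (s in v$states) xml2::xml_add_child(vn, "OUTCOME", s)
  }
  for (v in network$structure$nodes) {
    dn <- xml2::xml_add_child(nw, "DEFINITION")
    xml2::xml_add_child(dn, "FOR", v)
    for (p in network$structure$parents[[v]])
      xml2::xml_add_child(dn, "GIVEN", p)
    rows <- cpt_to_rows(network$cpts[[v]])
    xml2::xml_add_child(dn, "TABLE",
                        paste(format(t(rows), digits = 17, trim = TRUE,
                                     scientific = FALSE),
                              collapse = " "))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname write_xmlbif
#' @export
read_xmlbif <- function(path, target = NULL) {
  doc <- xml2::read_xml(path)
  vars <- xml2::xml_find_all(doc, ".//VARIABLE")
  specs <- lapply(vars, function(vn)
    variable_spec(xml2::xml_text(xml2::xml_find_first(vn, "./NAME")),
                  xml2::xml_text(xml2::xml_find_all(vn, "./OUTCOME"))))
  nms <- vapply(specs, function(s) s$name, character(1))
  if (is.null(target))
    target <- if ("HRUB" %in% nms) "HRUB" else nms[length(nms)]
  scheme <- variable_scheme(specs, target = target)
  defs <- xml2::xml_find_all(doc, ".//DEFINITION")
  parents <- list()
  tables <- list()
  for (dn in defs) {
    child <- xml2::xml_text(xml2::xml_find_first(dn, "./FOR"))
    given <- xml2::xml_text(xml2::xml_find_all(dn, "./GIVEN"))
    parents[[child]] <- given
    tables[[child]] <- as.numeric(strsplit(
      trimws(xml2::xml_text(xml2::xml_find_first(dn, "./TABLE"))),
      "\\s+")[[1]])
  }
  st <- bn_structure(parents[nms])
  card <- scheme_card(scheme)
  cpts <- lapply(nms, function(v) {
    r <- card[[v]]
    rows <- matrix(tables[[v]], ncol = r, byrow = TRUE)
    make_cpt(v, parents[[v]], scheme, rows = rows)
  })
  names(cpts) <- nms
  bn_network(scheme, st, cpts)
}
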