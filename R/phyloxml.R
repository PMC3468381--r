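# phyloXML object model and I/O. Element classes mirror the phyloXML
# specification; unknown elements are preserved verbatim (as XML text in
# `extras`) so third-party documents survive a convert cycle.

phyloxml_ns <- "http://www.phyloxml.org"

# closed rank vocabulary from the phyloXML specification
.pxml_ranks <- c(
  "domain", "superkingdom", "kingdom", "subkingdom", "branch", "infrakingdom",
  "superphylum", "phylum", "subphylum", "infraphylum", "microphylum",
  "superdivision", "division", "subdivision", "infradivision", "superclass",
  "class", "subclass", "infraclass", "superlegion", "legion", "sublegion",
  "infralegion", "supercohort", "cohort", "subcohort", "infracohort",
  "superorder", "order", "suborder", "superfamily", "family", "subfamily",
  "supertribe", "tribe", "subtribe", "infratribe", "genus", "subgenus",
  "superspecies", "species", "subspecies", "variety", "subvariety", "form",
  "subform", "cultivar", "unknown", "other")

#' Taxonomy annotation
#'
#' @param code Taxonomy code (e.g. `"OCTVU"`).
#' @param scientific_name,rank,common_names Further taxonomy fields; `rank`
#'   must come from the specification's closed vocabulary (warning
#'   otherwise).
#' @param id,id_provider Identifier and its provider (e.g. `"ncbi"`).
#' @param uri Optional [phylo_uri()].
#' @return An object of class `"taxonomy"`.
#' @export
taxonomy <- function(code = NULL, scientific_name = NULL, rank = NULL,
                     common_names = character(0), id = NULL,
                     id_provider = NULL, uri = NULL) {
  if (!is.null(rank) && !rank %in% .pxml_ranks) {
    warning("taxonomy rank '", rank, "' is not in the phyloXML vocabulary",
            call. = FALSE)
  }
  structure(list(code = code, scientific_name = scientific_name, rank = rank,
                 common_names = as.character(common_names), id = id,
                 id_provider = id_provider, uri = uri),
            class = "taxonomy")
}

#' Protein domain within a sequence
#'
#' Coordinates are 1-based inclusive, per the phyloXML specification (note
#' the off-by-one risk against 0-based conventions elsewhere).
#'
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`.
#' @param confidence Optional confidence (e.g. an E-value).
#' @param value Domain name/value text.
#' @param id Optional identifier.
#' @return An object of class `"protein_domain"`.
#' @export
protein_domain <- function(start, end, confidence = NULL, value = NULL,
                           id = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || end < start) {
    stop("protein domain requires 1 <= start <= end", call. = FALSE)
  }
  structure(list(start = start, end = end,
                 confidence = if (is.null(confidence)) NULL else as.numeric(confidence),
                 value = value, id = id),
            class = "protein_domain")
}

#' Molecular sequence annotation
#'
#' @param type One of `"dna"`, `"rna"`, `"protein"`.
#' @param symbol,name Short symbol and full name.
#' @param accession,accession_source Accession and its source database.
#' @param mol_seq The sequence text.
#' @param is_aligned Whether `mol_seq` is aligned (gaps included).
#' @param domain_architecture Optional `list(length =, domains = list(...))`
#'   of [protein_domain()] objects.
#' @return An object of class `"mol_sequence"`.
#' @export
mol_sequence <- function(type = NULL, symbol = NULL, accession = NULL,
                         accession_source = NULL, name = NULL, mol_seq = NULL,
                         is_aligned = FALSE, domain_architecture = NULL) {
  if (!is.null(type)) {
    type <- match.arg(type, c("dna", "rna", "protein"))
    if (!is.null(mol_seq)) {
      alpha <- switch(type,
                      dna = "^[ACGTNacgtn.~?*-]*$",
                      rna = "^[ACGUNacgun.~?*-]*$",
                      protein = "^[A-Za-z.~?*-]*$")
      if (!grepl(alpha, mol_seq)) {
        warning("sequence text does not match the ", type, " alphabet",
                call. = FALSE)
      }
    }
  }
  if (!is.null(domain_architecture)) {
    len <- domain_architecture$length
    for (d in domain_architecture$domains %||% list()) {
      if (!is.null(len) && d$end > len) {
        stop("protein domain [", d$start, ",", d$end,
             "] exceeds sequence length ", len, call. = FALSE)
      }
    }
  }
  structure(list(type = type, symbol = symbol, accession = accession,
                 accession_source = accession_source, name = name,
                 mol_seq = mol_seq, is_aligned = isTRUE(is_aligned),
                 domain_architecture = domain_architecture),
            class = "mol_sequence")
}

#' Confidence (support) value
#'
#' @param value Numeric support value.
#' @param type Kind of support, e.g. `"bootstrap"`, `"posterior"`.
#' @return An object of class `"confidence"`.
#' @export
confidence_value <- function(value, type = "unknown") {
  structure(list(value = as.numeric(value), type = type),
            class = "confidence")
}

#' Speciation/duplication/loss events at a clade
#'
#' @param speciations,duplications,losses Non-negative integer counts.
#' @param type Event type text.
#' @return An object of class `"clade_events"`.
#' @export
clade_events <- function(speciations = NULL, duplications = NULL,
                         losses = NULL, type = NULL) {
  for (v in list(speciations, duplications, losses)) {
    if (!is.null(v) && (is.na(as.integer(v)) || as.integer(v) < 0L)) {
      stop("event counts must be non-negative integers", call. = FALSE)
    }
  }
  structure(list(speciations = if (is.null(speciations)) NULL else as.integer(speciations),
                 duplications = if (is.null(duplications)) NULL else as.integer(duplications),
                 losses = if (is.null(losses)) NULL else as.integer(losses),
                 type = type),
            class = "clade_events")
}

#' Typed property annotation
#'
#' @param value Property value (stored as text).
#' @param ref Namespaced reference, e.g. `"NOAA:depth"`.
#' @param applies_to What the property applies to (`"clade"`, `"node"`, ...).
#' @param datatype XSD datatype, e.g. `"xsd:integer"`.
#' @param unit Optional unit reference.
#' @return An object of class `"phylo_property"`.
#' @export
phylo_property <- function(value, ref, applies_to = "clade",
                           datatype = "xsd:string", unit = NULL) {
  structure(list(value = as.character(value), ref = ref,
                 applies_to = applies_to, datatype = datatype, unit = unit),
            class = "phylo_property")
}

#' URI annotation
#'
#' @param value The URI text.
#' @param desc,type Optional description and type.
#' @return An object of class `"phylo_uri"`.
#' @export
phylo_uri <- function(value, desc = NULL, type = NULL) {
  structure(list(value = value, desc = desc, type = type),
            class = "phylo_uri")
}

#' Construct a phyloXML phylogeny
#'
#' A phylogeny extends [phylo_tree()] with a required rootedness flag,
#' optional name/id/description, tree-level confidences and properties, and
#' verbatim-preserved foreign elements.
#'
#' @param root Root clade (may carry phyloXML annotations).
#' @param rooted Required rootedness flag (always serialized).
#' @param name,id,description Optional metadata.
#' @param confidences List of [confidence_value()].
#' @param properties List of [phylo_property()].
#' @param extras Character vector of foreign XML elements, kept verbatim.
#' @return An object of class `c("phylogeny", "phylo_tree")`.
#' @export
phylogeny <- function(root, rooted, name = NULL, id = NULL,
                      description = NULL, confidences = list(),
                      properties = list(), extras = character(0)) {
  out <- phylo_tree(root, rooted = rooted, id = id, name = name)
  out$description <- description
  out$confidences <- confidences
  out$properties <- properties
  out$extras <- extras
  class(out) <- c("phylogeny", "phylo_tree")
  out
}

# --- parsing ----------------------------------------------------------------

xml_text1 <- function(node, xpath) {
  hit <- xml2::xml_find_first(node, xpath)
  if (inherits(hit, "xml_missing")) NULL else xml2::xml_text(hit)
}

xml_num1 <- function(node, xpath) {
  t <- xml_text1(node, xpath)
  if (is.null(t)) NULL else as.numeric(t)
}

attr_or_null <- function(node, name) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) NULL else v
}

parse_taxonomy_xml <- function(node) {
  idn <- xml2::xml_find_first(node, "./id")
  uri <- xml2::xml_find_first(node, "./uri")
  taxonomy(
    code = xml_text1(node, "./code"),
    scientific_name = xml_text1(node, "./scientific_name"),
    rank = xml_text1(node, "./rank"),
    common_names = xml2::xml_text(xml2::xml_find_all(node, "./common_name")),
    id = if (inherits(idn, "xml_missing")) NULL else xml2::xml_text(idn),
    id_provider = if (inherits(idn, "xml_missing")) NULL else
      attr_or_null(idn, "provider"),
    uri = if (inherits(uri, "xml_missing")) NULL else
      phylo_uri(xml2::xml_text(uri), desc = attr_or_null(uri, "desc"),
                type = attr_or_null(uri, "type"))
  )
}

parse_domain_xml <- function(node) {
  protein_domain(
    start = as.integer(xml2::xml_attr(node, "from")),
    end = as.integer(xml2::xml_attr(node, "to")),
    confidence = {
      v <- attr_or_null(node, "confidence")
      if (is.null(v)) NULL else as.numeric(v)
    },
    id = attr_or_null(node, "id"),
    value = xml2::xml_text(node)
  )
}

parse_sequence_xml <- function(node) {
  acc <- xml2::xml_find_first(node, "./accession")
  mseq <- xml2::xml_find_first(node, "./mol_seq")
  da <- xml2::xml_find_first(node, "./domain_architecture")
  suppressWarnings(mol_sequence(
    type = attr_or_null(node, "type"),
    symbol = xml_text1(node, "./symbol"),
    accession = if (inherits(acc, "xml_missing")) NULL else xml2::xml_text(acc),
    accession_source = if (inherits(acc, "xml_missing")) NULL else
      attr_or_null(acc, "source"),
    name = xml_text1(node, "./name"),
    mol_seq = if (inherits(mseq, "xml_missing")) NULL else xml2::xml_text(mseq),
    is_aligned = !inherits(mseq, "xml_missing") &&
      identical(xml2::xml_attr(mseq, "is_aligned"), "true"),
    domain_architecture = if (inherits(da, "xml_missing")) NULL else list(
      length = as.integer(xml2::xml_attr(da, "length")),
      domains = lapply(xml2::xml_find_all(da, "./domain"), parse_domain_xml)
    )
  ))
}

parse_events_xml <- function(node) {
  int_or_null <- function(xp) {
    t <- xml_text1(node, xp)
    if (is.null(t)) NULL else as.integer(t)
  }
  clade_events(speciations = int_or_null("./speciations"),
               duplications = int_or_null("./duplications"),
               losses = int_or_null("./losses"),
               type = xml_text1(node, "./type"))
}

parse_property_xml <- function(node) {
  phylo_property(value = xml2::xml_text(node),
                 ref = attr_or_null(node, "ref"),
                 applies_to = attr_or_null(node, "applies_to"),
                 datatype = attr_or_null(node, "datatype"),
                 unit = attr_or_null(node, "unit"))
}

parse_uri_xml <- function(node) {
  phylo_uri(xml2::xml_text(node), desc = attr_or_null(node, "desc"),
            type = attr_or_null(node, "type"))
}

.pxml_known_clade_children <- c(
  "name", "branch_length", "confidence", "width", "color", "taxonomy",
  "sequence", "events", "property", "uri", "clade")

parse_clade_xml <- function(node) {
  bl <- attr_or_null(node, "branch_length")
  if (is.null(bl)) bl <- xml_text1(node, "./branch_length")
  color_node <- xml2::xml_find_first(node, "./color")
  confs <- lapply(xml2::xml_find_all(node, "./confidence"), function(cn) {
    confidence_value(as.numeric(xml2::xml_text(cn)),
                     type = attr_or_null(cn, "type") %||% "unknown")
  })
  kids <- lapply(xml2::xml_find_all(node, "./clade"), parse_clade_xml)
  extras <- vapply(
    Filter(function(ch) !xml2::xml_name(ch) %in% .pxml_known_clade_children,
           as.list(xml2::xml_children(node))),
    as.character, character(1))
  clade(
    name = xml_text1(node, "./name"),
    branch_length = if (is.null(bl)) NULL else as.numeric(bl),
    confidence = if (length(confs) > 0) confs[[1]]$value else NULL,
    children = kids,
    color = if (inherits(color_node, "xml_missing")) NULL else branch_color(
      as.integer(xml2::xml_text(xml2::xml_find_first(color_node, "./red"))),
      as.integer(xml2::xml_text(xml2::xml_find_first(color_node, "./green"))),
      as.integer(xml2::xml_text(xml2::xml_find_first(color_node, "./blue")))),
    width = xml_num1(node, "./width"),
    taxonomies = lapply(xml2::xml_find_all(node, "./taxonomy"),
                        parse_taxonomy_xml),
    sequences = lapply(xml2::xml_find_all(node, "./sequence"),
                       parse_sequence_xml),
    confidences = confs,
    events = {
      ev <- xml2::xml_find_first(node, "./events")
      if (inherits(ev, "xml_missing")) NULL else parse_events_xml(ev)
    },
    properties = lapply(xml2::xml_find_all(node, "./property"),
                        parse_property_xml),
    uris = lapply(xml2::xml_find_all(node, "./uri"), parse_uri_xml),
    extras = extras
  )
}

#' Parse a phyloXML document
#'
#' Yields one [phylogeny()] per `phylogeny` element, with all implemented
#' phyloXML element types populated and unrecognized elements preserved
#' verbatim in `extras`. XML well-formedness errors propagate from the XML
#' layer with position information; a phylogeny without the required
#' `rooted` attribute is an error naming the phylogeny.
#'
#' @param source File path, connection, or XML text.
#' @return List of [phylogeny()] objects in document order.
#' @export
parse_phyloxml <- function(source) {
  doc <- xml2::read_xml(source)
  xml2::xml_ns_strip(doc)
  phylos <- xml2::xml_find_all(doc, "./phylogeny")
  lapply(phylos, function(pn) {
    nm <- xml_text1(pn, "./name")
    rooted <- attr_or_null(pn, "rooted")
    if (is.null(rooted)) {
      stop("phylogeny '", nm %||% "(unnamed)",
           "' is missing the required 'rooted' attribute", call. = FALSE)
    }
    clade_node <- xml2::xml_find_first(pn, "./clade")
    root <- if (inherits(clade_node, "xml_missing")) clade()
            else parse_clade_xml(clade_node)
    known <- c("name", "id", "description", "confidence", "property", "clade")
    extras <- vapply(
      Filter(function(ch) !xml2::xml_name(ch) %in% known,
             as.list(xml2::xml_children(pn))),
      as.character, character(1))
    phylogeny(
      root = root,
      rooted = identical(rooted, "true"),
      name = nm,
      id = xml_text1(pn, "./id"),
      description = xml_text1(pn, "./description"),
      confidences = lapply(xml2::xml_find_all(pn, "./confidence"), function(cn)
        confidence_value(as.numeric(xml2::xml_text(cn)),
                         type = attr_or_null(cn, "type") %||% "unknown")),
      properties = lapply(xml2::xml_find_all(pn, "./property"),
                          parse_property_xml),
      extras = extras
    )
  })
}

# --- serialization ----------------------------------------------------------

add_text_child <- function(parent, name, value, ...) {
  if (is.null(value)) return(invisible(NULL))
  node <- xml2::xml_add_child(parent, name, ...)
  xml2::xml_text(node) <- as.character(value)
  invisible(node)
}

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

write_confidence_xml <- function(parent, cf) {
  add_text_child(parent, "confidence", fmt_num(cf$value),
                 type = cf$type %||% "unknown")
}

write_property_xml <- function(parent, pr) {
  do.call(add_text_child,
          c(list(parent, "property", pr$value),
            drop_null(list(ref = pr$ref, unit = pr$unit,
                           datatype = pr$datatype,
                           applies_to = pr$applies_to))))
}

write_uri_xml <- function(parent, u) {
  do.call(add_text_child,
          c(list(parent, "uri", u$value),
            drop_null(list(desc = u$desc, type = u$type))))
}

write_taxonomy_xml <- function(parent, tx) {
  node <- xml2::xml_add_child(parent, "taxonomy")
  if (!is.null(tx$id)) {
    do.call(add_text_child,
            c(list(node, "id", tx$id),
              drop_null(list(provider = tx$id_provider))))
  }
  add_text_child(node, "code", tx$code)
  add_text_child(node, "scientific_name", tx$scientific_name)
  for (cn in tx$common_names) add_text_child(node, "common_name", cn)
  add_text_child(node, "rank", tx$rank)
  if (!is.null(tx$uri)) write_uri_xml(node, tx$uri)
  invisible(node)
}

write_sequence_xml <- function(parent, sq) {
  node <- do.call(xml2::xml_add_child,
                  c(list(parent, "sequence"), drop_null(list(type = sq$type))))
  add_text_child(node, "symbol", sq$symbol)
  if (!is.null(sq$accession)) {
    do.call(add_text_child,
            c(list(node, "accession", sq$accession),
              drop_null(list(source = sq$accession_source))))
  }
  add_text_child(node, "name", sq$name)
  if (!is.null(sq$mol_seq)) {
    add_text_child(node, "mol_seq", sq$mol_seq,
                   is_aligned = if (sq$is_aligned) "true" else "false")
  }
  if (!is.null(sq$domain_architecture)) {
    da <- xml2::xml_add_child(node, "domain_architecture",
                              length = as.character(sq$domain_architecture$length))
    for (d in sq$domain_architecture$domains %||% list()) {
      do.call(add_text_child,
              c(list(da, "domain", d$value %||% ""),
                drop_null(list(
                  from = as.character(d$start), to = as.character(d$end),
                  confidence = if (is.null(d$confidence)) NULL else
                    fmt_num(d$confidence),
                  id = d$id))))
    }
  }
  invisible(node)
}

write_events_xml <- function(parent, ev) {
  node <- xml2::xml_add_child(parent, "events")
  add_text_child(node, "type", ev$type)
  add_text_child(node, "duplications", ev$duplications)
  add_text_child(node, "speciations", ev$speciations)
  add_text_child(node, "losses", ev$losses)
  invisible(node)
}

write_clade_xml <- function(parent, cl) {
  node <- if (is.null(cl$branch_length)) {
    xml2::xml_add_child(parent, "clade")
  } else {
    xml2::xml_add_child(parent, "clade",
                        branch_length = fmt_num(cl$branch_length))
  }
  add_text_child(node, "name", cl$name)
  confs <- cl$confidences %||% list()
  if (length(confs) == 0 && !is.null(cl$confidence)) {
    confs <- list(confidence_value(cl$confidence, "unknown"))
  }
  for (cf in confs) write_confidence_xml(node, cf)
  add_text_child(node, "width", if (is.null(cl$width)) NULL else fmt_num(cl$width))
  if (!is.null(cl$color)) {
    cnode <- xml2::xml_add_child(node, "color")
    add_text_child(cnode, "red", cl$color$red)
    add_text_child(cnode, "green", cl$color$green)
    add_text_child(cnode, "blue", cl$color$blue)
  }
  for (tx in cl$taxonomies %||% list()) write_taxonomy_xml(node, tx)
  for (sq in cl$sequences %||% list()) write_sequence_xml(node, sq)
  if (!is.null(cl$events)) write_events_xml(node, cl$events)
  for (pr in cl$properties %||% list()) write_property_xml(node, pr)
  for (u in cl$uris %||% list()) write_uri_xml(node, u)
  for (ex in cl$extras %||% character(0)) {
    xml2::xml_add_child(node, xml2::read_xml(ex))
  }
  for (ch in cl$children) write_clade_xml(node, ch)
  invisible(node)
}

#' Serialize phylogenies as a phyloXML document
#'
#' Produces a namespace-correct document that parses back to structurally
#' identical phylogenies, including preserved foreign elements. Branch
#' lengths are written as the `branch_length` attribute (and accepted as
#' attribute or child element on read); numeric values are written at full
#' round-trip precision.
#'
#' @param phylogenies A tree/phylogeny or list of them; plain trees are
#'   promoted with [as_phyloxml()].
#' @return phyloXML document text.
#' @export
serialize_phyloxml <- function(phylogenies) {
  if (inherits(phylogenies, "phylo_tree") || inherits(phylogenies, "clade")) {
    phylogenies <- list(phylogenies)
  }
  doc <- xml2::xml_new_root("phyloxml", xmlns = phyloxml_ns)
  for (tr in phylogenies) {
    ph <- as_phyloxml(tr)
    pnode <- xml2::xml_add_child(doc, "phylogeny",
                                 rooted = if (isTRUE(ph$rooted)) "true" else "false")
    add_text_child(pnode, "name", ph$name)
    add_text_child(pnode, "id", ph$id)
    add_text_child(pnode, "description", ph$description)
    write_clade_xml(pnode, ph$root)
    for (cf in ph$confidences %||% list()) write_confidence_xml(pnode, cf)
    for (pr in ph$properties %||% list()) write_property_xml(pnode, pr)
    for (ex in ph$extras %||% character(0)) {
      xml2::xml_add_child(pnode, xml2::read_xml(ex))
    }
  }
  as.character(doc)
}

#' Promote a tree to its phyloXML equivalent
#'
#' Lossless promotion: names, branch lengths, colours and widths carry
#' over, and a bare clade confidence becomes a `Confidence` element of type
#' `"unknown"`. Promoting an existing phylogeny returns it unchanged.
#'
#' @param x A tree or clade.
#' @return A [phylogeny()].
#' @export
as_phyloxml <- function(x) {
  if (inherits(x, "phylogeny")) return(x)
  promote <- function(cl) {
    if (is.null(cl$confidences) && !is.null(cl$confidence)) {
      cl$confidences <- list(confidence_value(cl$confidence, "unknown"))
    }
    cl$children <- lapply(cl$children, promote)
    cl
  }
  root <- promote(root_of(x))
  if (inherits(x, "phylo_tree")) {
    phylogeny(root, rooted = isTRUE(x$rooted), name = x$name, id = x$id)
  } else {
    phylogeny(root, rooted = FALSE)
  }
}

#' Extract an alignment from the aligned sequences in a tree
#'
#' Collects, in preorder, one row per clade carrying a molecular sequence
#' flagged as aligned. All rows must have equal length.
#'
#' @param x A phylogeny (or any tree whose clades carry [mol_sequence()]
#'   annotations).
#' @return Named character vector of aligned sequences (possibly empty,
#'   with a warning, when no clade has an aligned sequence).
#' @export
to_alignment <- function(x) {
  rows <- character(0)
  for (cl in find_clades(x)) {
    for (sq in cl$sequences %||% list()) {
      if (isTRUE(sq$is_aligned) && !is.null(sq$mol_seq)) {
        nm <- sq$name %||% cl$name %||% sprintf("row%d", length(rows) + 1L)
        rows[nm] <- sq$mol_seq
      }
    }
  }
  if (length(rows) == 0) {
    warning("no aligned sequences in this tree; returning empty alignment",
            call. = FALSE)
    return(rows)
  }
  lens <- nchar(rows)
  if (length(unique(lens)) > 1) {
    bad <- names(rows)[lens != lens[1]]
    stop("aligned sequences have unequal lengths: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  rows
}
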