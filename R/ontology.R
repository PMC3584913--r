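#' Construct a function-ontology DAG
#'
#' Builds the directed acyclic graph of function terms used throughout the
#' package: terms linked to their parents by `is_a` edges, partitioned into
#' namespaces (molecular function `"MF"`, biological process `"BP"`), each
#' namespace rooted at a single term. Annotations attached to a term are
#' implicitly inherited by all its ancestors (the true-path rule), so the DAG
#' carries precomputed ancestor closures.
#'
#' @param edges A data frame with columns `term`, `parent` and `namespace`.
#'   One row per `is_a` edge; root terms appear with `parent = NA`. A term
#'   with several parents appears on several rows.
#'
#' @return An object of class `onto_dag` with components `terms`, `parents`
#'   (named list), `namespace` (named character), `roots` (named character,
#'   one per namespace) and `ancestors` (named list of ancestor closures,
#'   each including the term itself).
#'
#' @examples
#' dag <- ontology_dag(tibble::tibble(
#'   term = c("MF:0", "MF:1", "MF:2"),
#'   parent = c(NA, "MF:0", "MF:1"),
#'   namespace = "MF"
#' ))
#' term_ancestors(dag, "MF:2")
#' @export
ontology_dag <- function(edges) {
  edges <- as_tibble(edges)
  stopifnot(all(c("term", "parent", "namespace") %in% names(edges)))
  edges <- distinct(edges, term, parent, namespace)

  ns_map <- distinct(edges, term, namespace)
  if (anyDuplicated(ns_map$term) > 0) {
    dup <- ns_map$term[duplicated(ns_map$term)]
    abort(paste0("term assigned to more than one namespace: ",
                 paste(unique(dup), collapse = ", ")))
  }
  terms <- ns_map$term
  namespace <- set_names(ns_map$namespace, terms)

  unknown <- setdiff(edges$parent[!is.na(edges$parent)], terms)
  if (length(unknown) > 0) {
    abort(paste0("unknown parent id(s): ", paste(unknown, collapse = ", ")))
  }

  parent_edges <- filter(edges, !is.na(parent))
  cross <- parent_edges[namespace[parent_edges$term] !=
                          namespace[parent_edges$parent], ]
  if (nrow(cross) > 0) {
    abort(paste0("is_a edge crosses namespaces: ",
                 cross$term[1], " -> ", cross$parent[1]))
  }

  parents <- split(parent_edges$parent, factor(parent_edges$term, levels = terms))
  parents <- lapply(parents, function(x) sort(unique(x)))

  roots_all <- terms[lengths(parents) == 0]
  roots <- vapply(split(roots_all, namespace[roots_all]), function(r) {
    if (length(r) != 1) {
      abort(paste0("namespace must have exactly one root, found: ",
                   paste(r, collapse = ", ")))
    }
    r
  }, character(1))
  if (!setequal(names(roots), unique(namespace))) {
    abort("every namespace needs a root term (a term with no parent)")
  }

  dag <- structure(
    list(terms = terms, parents = parents, namespace = namespace,
         roots = roots),
    class = "onto_dag"
  )
  dag$ancestors <- compute_closures(dag)
  dag
}

# topological order (parents before children); names an edge of a cycle on failure
topological_order <- function(dag) {
  indeg <- lengths(dag$parents)
  children <- invert_parents(dag)
  queue <- dag$terms[indeg == 0]
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(dag$terms)) {
    left <- setdiff(dag$terms, out)
    t1 <- left[1]
    p1 <- intersect(dag$parents[[t1]], left)[1]
    abort(paste0("cycle detected in ontology involving edge ",
                 t1, " is_a ", p1))
  }
  out
}

invert_parents <- function(dag) {
  children <- set_names(vector("list", length(dag$terms)), dag$terms)
  for (t in names(dag$parents)) {
    for (p in dag$parents[[t]]) children[[p]] <- c(children[[p]], t)
  }
  children
}

compute_closures <- function(dag) {
  ord <- topological_order(dag)
  anc <- set_names(vector("list", length(dag$terms)), dag$terms)
  for (t in ord) {
    up <- unlist(anc[dag$parents[[t]]], use.names = FALSE)
    anc[[t]] <- unique(c(t, up))
  }
  anc
}

#' @export
print.onto_dag <- function(x, ...) {
  ns <- table(x$namespace)
  cat("<onto_dag> ", length(x$terms), " terms (",
      paste(names(ns), ns, sep = ": ", collapse = ", "), ")\n", sep = "")
  cat("roots: ", paste(names(x$roots), x$roots, sep = " = ", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Ancestor closure of ontology terms
#'
#' Returns, for each requested term, the set of its ancestors under `is_a`
#' edges. By convention the closure includes the term itself, so the closure
#' of a namespace root is the root alone.
#'
#' @param dag An [ontology_dag()].
#' @param terms Character vector of term ids.
#' @param include_self Include each term in its own closure (default `TRUE`;
#'   this is the convention under which the Lin similarity of a term with
#'   itself is 1).
#' @return A named list of character vectors.
#' @export
term_ancestors <- function(dag, terms, include_self = TRUE) {
  check_dag(dag)
  miss <- setdiff(terms, dag$terms)
  if (length(miss) > 0) {
    abort(paste0("unknown term id(s): ", paste(miss, collapse = ", ")))
  }
  out <- dag$ancestors[terms]
  if (!include_self) out <- Map(setdiff, out, terms)
  out
}

check_dag <- function(dag) {
  if (!inherits(dag, "onto_dag")) abort("`dag` must be an <onto_dag>")
  invisible(dag)
}

#' Read an ontology from an OBO flat file
#'
#' Parses the `[Term]` stanzas of an OBO 1.2/1.4 file, keeping the `id`,
#' `name`, `namespace`, `is_a` and `is_obsolete` tags. Obsolete terms are
#' dropped; relations other than `is_a` (e.g. `part_of` in
#' `relationship:` lines) are ignored, so the resulting DAG encodes the
#' minimal true-path relation only.
#'
#' Namespaces containing "function" map to `"MF"` and those containing
#' "process" to `"BP"`; any other namespace string is kept verbatim.
#'
#' @param path Path to an OBO file.
#' @return An [ontology_dag()].
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (length(starts) == 0) abort("no stanzas found in OBO file")
  ends <- c(starts[-1] - 1L, length(lines))
  records <- list()
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    body <- lines[(starts[i] + 1L):ends[i]]
    tag <- sub("^([a-z_]+):.*$", "\\1", body)
    val <- trimws(sub("^[a-z_]+:", "", body))
    id <- val[tag == "id"][1]
    if (is.na(id)) next
    if (any(tag == "is_obsolete" & grepl("true", val))) next
    is_a <- val[tag == "is_a"]
    is_a <- trimws(sub("!.*$", "", is_a))   # strip trailing "! name" comments
    ns <- val[tag == "namespace"][1]
    records[[length(records) + 1L]] <- tibble(
      term = id,
      parent = if (length(is_a) > 0) is_a else NA_character_,
      namespace = if (is.na(ns)) NA_character_ else ns
    )
  }
  if (length(records) == 0) abort("no non-obsolete [Term] stanzas in OBO file")
  edges <- bind_rows(records)
  edges$namespace <- normalize_namespace(edges$namespace)
  # inherit a missing namespace from the majority namespace (single-ns files)
  if (anyNA(edges$namespace)) {
    ns_tab <- table(edges$namespace)
    if (length(ns_tab) == 0) abort("OBO file carries no namespace tags")
    edges$namespace[is.na(edges$namespace)] <- names(which.max(ns_tab))
  }
  ontology_dag(edges)
}

normalize_namespace <- function(ns) {
  out <- ns
  out[grepl("function", ns, ignore.case = TRUE)] <- "MF"
  out[grepl("process", ns, ignore.case = TRUE)] <- "BP"
  out
}

#' Write an ontology as a minimal OBO file
#'
#' Emits one `[Term]` stanza per term with `id`, `namespace` and `is_a`
#' tags — the subset [read_obo()] consumes. Round-trips exactly.
#'
#' @param dag An [ontology_dag()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  check_dag(dag)
  ns_long <- c(MF = "molecular_function", BP = "biological_process")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in dag$terms) {
    ns <- dag$namespace[[t]]
    lines <- c("[Term]",
               paste0("id: ", t),
               paste0("name: ", t),
               paste0("namespace: ", if (ns %in% names(ns_long)) ns_long[[ns]] else ns))
    for (p in dag$parents[[t]]) lines <- c(lines, paste0("is_a: ", p))
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Cluster ontology terms by position in the DAG
#'
#' Partitions terms for cluster-specific weight learning: at the `"root"`
#' level every term maps to its namespace (MF vs BP); at the `"first"` level
#' every term maps to the direct child of its namespace root that subsumes
#' it. A term reachable from several first-level children is assigned the
#' lexicographically smallest of them; the roots themselves map to their
#' namespace.
#'
#' @param dag An [ontology_dag()].
#' @param level `"root"` or `"first"`.
#' @return A tibble with columns `term` and `cluster`.
#' @export
cluster_terms <- function(dag, level = c("root", "first")) {
  check_dag(dag)
  level <- arg_match(level)
  if (level == "root") {
    return(tibble(term = dag$terms, cluster = unname(dag$namespace[dag$terms])))
  }
  first_level <- unlist(lapply(dag$roots, function(r) {
    names(Filter(function(ps) r %in% ps, dag$parents))
  }), use.names = FALSE)
  cl <- vapply(dag$terms, function(t) {
    if (t %in% dag$roots) return(unname(dag$namespace[[t]]))
    hit <- sort(intersect(dag$ancestors[[t]], first_level))
    if (length(hit) == 0) unname(dag$namespace[[t]]) else hit[1]
  }, character(1))
  tibble(term = dag$terms, cluster = unname(cl))
}
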