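#' Configuration for the synthetic benchmark generator
#'
#' The generator plants a latent functional-module structure: proteins
#' belong to modules, modules own characteristic leaf terms, and all three
#' data sources (sequence identity, expression, PPI) carry signal
#' proportional to shared function. Defaults define the package's standard
#' study conditions: 300 proteins, a two-namespace DAG of 60 terms,
#' per-source coverages (1.0, 0.46, 0.20) echoing the very different
#' coverage of real sequence/expression/PPI corpora, and moderate signal
#' strengths under which kNN label transfer is learnable but not trivial.
#'
#' @param n_proteins Number of proteins (default 300).
#' @param n_terms Total number of ontology terms across both namespaces
#'   (default 60; at least 3 per namespace).
#' @param dag_branching Children per internal term (default 3).
#' @param n_modules Latent functional modules (default 6).
#' @param n_samples Expression samples (default 40).
#' @param annotation_rate Fraction of proteins annotated (default 1).
#' @param signal Named signal strengths in `[0, 1]` for `seq`, `expr`,
#'   `ppi` (defaults 0.8, 0.6, 0.6).
#' @param coverage Named coverage fractions in `[0, 1]` for `seq`, `expr`,
#'   `ppi` (defaults 1.0, 0.46, 0.20).
#' @param multi_parent_rate Fraction of non-root terms receiving a second
#'   parent (default 0.1).
#' @param seed Master seed; every random draw is derived from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_proteins = 300, n_terms = 60,
                             dag_branching = 3, n_modules = 6,
                             n_samples = 40, annotation_rate = 1,
                             signal = c(seq = 0.8, expr = 0.6, ppi = 0.6),
                             coverage = c(seq = 1.0, expr = 0.46, ppi = 0.20),
                             multi_parent_rate = 0.1, seed = 1) {
  stopifnot(n_proteins >= 1, n_terms >= 6, dag_branching >= 1,
            n_modules >= 1, n_samples >= 3)
  rates <- c(annotation_rate, signal, coverage, multi_parent_rate)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  stopifnot(setequal(names(signal), c("seq", "expr", "ppi")),
            setequal(names(coverage), c("seq", "expr", "ppi")))
  structure(list(n_proteins = as.integer(n_proteins),
                 n_terms = as.integer(n_terms),
                 dag_branching = as.integer(dag_branching),
                 n_modules = as.integer(n_modules),
                 n_samples = as.integer(n_samples),
                 annotation_rate = annotation_rate,
                 signal = signal[c("seq", "expr", "ppi")],
                 coverage = coverage[c("seq", "expr", "ppi")],
                 multi_parent_rate = multi_parent_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# deterministic fan-out of the master seed, kept below 2^31
child_seed <- function(cfg, offset) {
  (cfg$seed * 7919L + offset * 104729L) %% 2147483647L
}

#' Generate a synthetic two-namespace ontology
#'
#' Builds an MF-like and a BP-like namespace (roots `MF:0000000`,
#' `BP:0000000`), growing each level with `dag_branching` children per
#' term until the term quota is met; a seeded fraction of non-root terms
#' receives a second parent chosen among earlier terms, so multi-parent
#' (and multi-first-level-ancestor) logic is exercised while acyclicity
#' holds by construction.
#'
#' @param cfg A [synthetic_config()].
#' @return An [ontology_dag()].
#' @export
make_ontology <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(child_seed(cfg, 1L), {
    per_ns <- c(MF = ceiling(cfg$n_terms / 2),
                BP = cfg$n_terms - ceiling(cfg$n_terms / 2))
    edges <- purrr::map_dfr(names(per_ns), function(ns) {
      n <- per_ns[[ns]]
      ids <- sprintf("%s:%07d", ns, seq_len(n) - 1L)
      root <- ids[1]
      rows <- list(tibble(term = root, parent = NA_character_, namespace = ns))
      if (n > 1) {
        # breadth-first: term i's parent is term floor((i-2)/branching)+1
        for (i in 2:n) {
          p <- ids[(i - 2L) %/% cfg$dag_branching + 1L]
          rows[[i]] <- tibble(term = ids[i], parent = p, namespace = ns)
        }
        # extra parents among strictly earlier non-parent terms
        extra_n <- floor(cfg$multi_parent_rate * (n - 1))
        if (extra_n > 0 && n > 3) {
          cand <- sample(3:n, min(extra_n, n - 2))
          for (i in cand) {
            p1 <- rows[[i]]$parent
            pool <- setdiff(ids[seq_len(i - 1L)], c(ids[i], p1))
            if (length(pool) > 0) {
              p2 <- sample(pool, 1)
              rows[[length(rows) + 1L]] <-
                tibble(term = ids[i], parent = p2, namespace = ns)
            }
          }
        }
      }
      bind_rows(rows)
    })
    ontology_dag(edges)
  })
}

dag_leaves <- function(dag) {
  has_child <- unique(unlist(dag$parents, use.names = FALSE))
  setdiff(dag$terms, has_child)
}

#' Generate synthetic protein annotations with planted module structure
#'
#' Each protein is assigned to one latent functional module; each module
#' owns a handful of characteristic leaf terms per namespace. An annotated
#' protein receives each of its module's core leaves with probability 0.6
#' and 1-2 random background leaves, for 1-5 leaf terms overall — so every
#' core leaf ends up annotating a sizeable share of its module and the
#' term-centric AUC is computable. The returned table is raw (leaves
#' only, `propagated = FALSE`).
#'
#' @param dag An [ontology_dag()] from [make_ontology()].
#' @param cfg A [synthetic_config()].
#' @return An [annotation_table()] with a `modules` attribute (named
#'   integer vector protein -> module).
#' @export
make_annotations <- function(dag, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(child_seed(cfg, 2L), {
    proteins <- sprintf("P%05d", seq_len(cfg$n_proteins))
    modules <- set_names(rep(seq_len(cfg$n_modules),
                             length.out = cfg$n_proteins), proteins)
    leaves <- dag_leaves(dag)
    core_per_module <- lapply(seq_len(cfg$n_modules), function(m) {
      sample(leaves, min(4L, length(leaves)))
    })
    annotated <- runif(cfg$n_proteins) <= cfg$annotation_rate
    rows <- list()
    for (i in seq_len(cfg$n_proteins)) {
      if (!annotated[i]) next
      core <- core_per_module[[modules[[i]]]]
      take <- core[runif(length(core)) < 0.6]
      bg <- sample(leaves, sample(1:2, 1))
      fts <- unique(c(take, bg))
      fts <- head(fts, 5)
      rows[[i]] <- tibble(protein = proteins[i], term = fts)
    }
    ann <- annotation_table(bind_rows(rows))
    attr(ann, "modules") <- modules
    ann
  })
}

#' Generate the three synthetic data sources
#'
#' Plants functional signal in all three sources, controlled per source by
#' `cfg$signal`:
#' * sequence identity = baseline noise plus a bonus proportional to the
#'   fraction of shared leaf annotations, scaled to \[0, 100\], symmetric,
#'   diagonal 100;
#' * expression profiles = the protein's module profile scaled by the
#'   signal strength plus Gaussian noise, so same-module proteins
#'   correlate;
#' * PPI edges drawn with a baseline probability elevated for pairs
#'   sharing annotations.
#' Each source covers only a seeded random subset of proteins
#' (`cfg$coverage`), emulating the very different coverages of real
#' corpora; sequence coverage defaults to complete.
#'
#' @param ann A [make_annotations()] table (raw leaves, with `modules`
#'   attribute).
#' @param cfg A [synthetic_config()].
#' @return A list with elements `identity` (matrix, percent identities),
#'   `expression` (proteins x samples matrix), `ppi` (tibble of edges) and
#'   `covered` (named list of covered protein ids per source).
#' @export
make_sources <- function(ann, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  proteins <- sort(unique(ann$protein))
  n <- length(proteins)
  modules <- attr(ann, "modules")[proteins]
  sets <- split(ann$term, factor(ann$protein, levels = proteins))
  shared <- matrix(0, n, n, dimnames = list(proteins, proteins))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sets[[i]]; b <- sets[[j]]
      s <- length(intersect(a, b)) / max(1, min(length(a), length(b)))
      shared[i, j] <- s; shared[j, i] <- s
    }
  }

  covered <- withr::with_seed(child_seed(cfg, 3L), {
    lapply(cfg$coverage, function(cv) {
      sort(sample(proteins, max(2, round(cv * n))))
    })
  })

  identity <- withr::with_seed(child_seed(cfg, 4L), {
    noise <- matrix(runif(n * n, 0, 25), n, n)
    noise <- (noise + t(noise)) / 2
    m <- 15 + noise + 55 * cfg$signal[["seq"]] * shared
    m <- round(pmin(pmax(m, 0), 100), 4)   # percent-identity precision
    dimnames(m) <- list(proteins, proteins)
    diag(m) <- 100
    m[covered$seq, covered$seq, drop = FALSE]
  })

  expression <- withr::with_seed(child_seed(cfg, 5L), {
    profiles <- matrix(rnorm(cfg$n_modules * cfg$n_samples),
                       cfg$n_modules, cfg$n_samples)
    s <- cfg$signal[["expr"]]
    e <- s * profiles[modules, , drop = FALSE] +
      (1 - s) * matrix(rnorm(n * cfg$n_samples), n, cfg$n_samples)
    e <- round(e, 6)
    dimnames(e) <- list(proteins,
                        sprintf("sample%03d", seq_len(cfg$n_samples)))
    e[covered$expr, , drop = FALSE]
  })

  ppi <- withr::with_seed(child_seed(cfg, 6L), {
    nodes <- covered$ppi
    idx <- which(upper.tri(shared[nodes, nodes, drop = FALSE]), arr.ind = TRUE)
    p_edge <- 0.02 + 0.5 * cfg$signal[["ppi"]] *
      shared[nodes, nodes][idx]
    draw <- runif(nrow(idx)) < p_edge
    tibble(protein_a = nodes[idx[draw, 1]], protein_b = nodes[idx[draw, 2]])
  })

  list(identity = identity, expression = expression, ppi = ppi,
       covered = covered)
}

#' Generate and optionally write a complete synthetic dataset
#'
#' Runs [make_ontology()], [make_annotations()] and [make_sources()] under
#' one configuration. When `dir` is given, writes the exact file formats
#' the readers consume — `ontology.obo`, `annotations.tsv`,
#' `identity.tsv`, `expression.tsv`, `ppi.tsv` — plus `manifest.json`
#' recording the configuration; the same seed always produces
#' byte-identical files.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed), or `NULL` to skip
#'   writing.
#' @return A list with `dag`, `ann` (raw annotations), `sources` and
#'   `files` (named paths, when written).
#' @export
simulate_dataset <- function(cfg = synthetic_config(), dir = NULL) {
  dag <- make_ontology(cfg)
  ann <- make_annotations(dag, cfg)
  sources <- make_sources(ann, cfg)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(
      ontology = file.path(dir, "ontology.obo"),
      annotations = file.path(dir, "annotations.tsv"),
      identity = file.path(dir, "identity.tsv"),
      expression = file.path(dir, "expression.tsv"),
      ppi = file.path(dir, "ppi.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    write_obo(dag, files[["ontology"]])
    write_annotations(ann, files[["annotations"]])
    write_matrix_tsv(sources$identity, files[["identity"]])
    write_matrix_tsv(sources$expression, files[["expression"]])
    readr::write_tsv(sources$ppi, files[["ppi"]])
    manifest <- unclass(cfg)
    manifest$signal <- as.list(manifest$signal)
    manifest$coverage <- as.list(manifest$coverage)
    jsonlite::write_json(manifest, files[["manifest"]],
                         auto_unbox = TRUE, digits = NA)
  }
  list(dag = dag, ann = ann, sources = sources, files = files)
}
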