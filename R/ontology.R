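#' Construct an OntologyGraph from term tables
#'
#' Low-level constructor used by [loadOBO()] and the toy-ontology generator.
#' Builds the child-to-parent `is_a` graph, verifies acyclicity, and
#' precomputes every term's depth (length of the shortest directed path up
#' to a root; roots have depth 0).
#'
#' @param termIds,termNames parallel character vectors.
#' @param synonyms list of data frames (`text`, `scope`) per term, or `NULL`.
#' @param parents list of character vectors of parent ids per term.
#' @param obsolete logical vector per term.
#' @return an [OntologyGraph-class] object.
#' @export
ontologyGraph <- function(termIds, termNames, synonyms = NULL,
                          parents = NULL, obsolete = NULL) {
  n <- length(termIds)
  if (is.null(synonyms))
    synonyms <- rep(list(data.frame(text = character(), scope = character(),
                                    stringsAsFactors = FALSE)), n)
  if (is.null(parents)) parents <- rep(list(character()), n)
  if (is.null(obsolete)) obsolete <- rep(FALSE, n)
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(parents[[i]]))
      cbind(termIds[i], parents[[i]]) else NULL
  }))
  g <- igraph::make_empty_graph(n = n, directed = TRUE)
  g <- igraph::set_vertex_attr(g, "name", value = termIds)
  if (!is.null(edges)) {
    unknown <- setdiff(unique(edges[, 2]), termIds)
    if (length(unknown))
      glStop(paste0("is_a parents not defined in ontology: ",
                    paste(unknown, collapse = ", ")), "geolabel_obo_error")
    g <- igraph::add_edges(g, t(edges))
  }
  if (n > 0 && !igraph::is_dag(g))
    glStop("ontology is_a graph contains a cycle", "geolabel_obo_error")
  roots <- termIds[vapply(parents, length, 1L) == 0L]
  depths <- if (n == 0) integer() else {
    d <- igraph::distances(g, v = termIds, to = roots, mode = "out")
    as.integer(apply(d, 1, min))
  }
  new("OntologyGraph", termIds = termIds, termNames = termNames,
      synonyms = synonyms, parents = parents, obsolete = obsolete,
      depths = depths, graph = g)
}

setMethod("show", "OntologyGraph", function(object) {
  cat("OntologyGraph with", length(object@termIds), "terms (",
      sum(vapply(object@parents, length, 1L) == 0L), "root(s),",
      sum(object@obsolete), "obsolete )\n")
  invisible(object)
})

#' @describeIn ontologyGraph term ids
#' @param x an `OntologyGraph`
#' @export
termIds <- function(x) x@termIds

#' @describeIn ontologyGraph primary names, named by term id
#' @export
termNames <- function(x) stats::setNames(x@termNames, x@termIds)

#' @describeIn ontologyGraph root term ids (terms with no parents)
#' @export
ontologyRoots <- function(x)
  x@termIds[vapply(x@parents, length, 1L) == 0L]

#' Load an OBO flat file
#'
#' Parses `[Term]` stanzas of an OBO 1.2/1.4 file: `id`, `name`,
#' `synonym: "text" SCOPE []` (all scopes kept and recorded), `is_a` and
#' `is_obsolete` lines. Stanzas missing an id or a name are skipped with a
#' warning; a cycle among `is_a` edges is a fatal error.
#'
#' @param path path to the OBO file.
#' @return an [OntologyGraph-class] object.
#' @export
loadOBO <- function(path) {
  if (!file.exists(path))
    glStop(paste0("OBO file not found: ", path), "geolabel_io_error")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  ## split into stanzas
  starts <- grep("^\\[", lines)
  termIds <- character(); termNames <- character()
  synonyms <- list(); parents <- list(); obsolete <- logical()
  if (length(starts)) {
    ends <- c(starts[-1] - 1L, length(lines))
    for (s in seq_along(starts)) {
      if (!identical(lines[starts[s]], "[Term]")) next
      body <- lines[(starts[s] + 1L):ends[s]]
      getv <- function(tag) {
        v <- sub(paste0("^", tag, ":\\s*"), "",
                 grep(paste0("^", tag, ":"), body, value = TRUE))
        sub("\\s*(!.*)?$", "", v)  # strip trailing comments
      }
      id <- getv("id"); nm <- getv("name")
      if (!length(id) || !length(nm) || !nzchar(id[1]) || !nzchar(nm[1])) {
        warning("OBO stanza without id or name skipped")
        next
      }
      synLines <- grep("^synonym:", body, value = TRUE)
      syn <- do.call(rbind, lapply(synLines, function(l) {
        m <- regmatches(l, regexec(
          "^synonym:\\s*\"(.*)\"\\s*([A-Z_]*)", l))[[1]]
        if (length(m) < 2) return(NULL)
        data.frame(text = m[2],
                   scope = if (length(m) >= 3 && nzchar(m[3]))
                     m[3] else "RELATED",
                   stringsAsFactors = FALSE)
      }))
      if (is.null(syn))
        syn <- data.frame(text = character(), scope = character(),
                          stringsAsFactors = FALSE)
      isa <- sub("\\s*\\{.*\\}$", "", getv("is_a"))
      obs <- any(grepl("^is_obsolete:\\s*true", body))
      termIds <- c(termIds, id[1]); termNames <- c(termNames, nm[1])
      synonyms <- c(synonyms, list(syn))
      parents <- c(parents, list(isa[nzchar(isa)]))
      obsolete <- c(obsolete, obs)
    }
  }
  ## obsolete terms may cite parents pruned elsewhere; drop dangling links
  parents <- lapply(parents, function(p) intersect(p, termIds))
  ontologyGraph(termIds, termNames, synonyms, parents, obsolete)
}

#' Write an OntologyGraph as an OBO flat file
#'
#' Serializes the graph so that [loadOBO()] round-trips it (term order,
#' names, synonyms with scope, `is_a` links and obsolete flags preserved).
#'
#' @param graph an [OntologyGraph-class] object.
#' @param path output path.
#' @export
writeOBO <- function(graph, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_along(graph@termIds)) {
    writeLines("[Term]", con)
    writeLines(paste0("id: ", graph@termIds[i]), con)
    writeLines(paste0("name: ", graph@termNames[i]), con)
    syn <- graph@synonyms[[i]]
    for (j in seq_len(nrow(syn)))
      writeLines(sprintf("synonym: \"%s\" %s []", syn$text[j], syn$scope[j]),
                 con)
    for (p in graph@parents[[i]])
      writeLines(paste0("is_a: ", p), con)
    if (graph@obsolete[i]) writeLines("is_obsolete: true", con)
    writeLines("", con)
  }
  invisible(path)
}

.termIndex <- function(graph, id) {
  i <- match(id, graph@termIds)
  if (anyNA(i))
    glStop(paste0("unknown ontology term(s): ",
                  paste(id[is.na(i)], collapse = ", ")),
           "geolabel_term_error")
  i
}

#' Depth of a term in the ontology
#'
#' Depth is the length of the *shortest* directed `is_a` path from the term
#' up to any root; roots have depth 0. Under multiple parentage the shortest
#' route wins, matching the "most general" reading used by shallowest-node
#' selection.
#'
#' @param graph an [OntologyGraph-class].
#' @param termId one or more term ids.
#' @return integer depth(s).
#' @export
termDepth <- function(graph, termId) {
  graph@depths[.termIndex(graph, termId)]
}

#' Shortest-path distance between two ontology terms
#'
#' `is_a` edges are treated as undirected, so the distance between siblings
#' is 2 (up to the shared parent and back down). `d(a, a) = 0`; terms in
#' different connected components are at distance `Inf`.
#'
#' @param graph an [OntologyGraph-class].
#' @param a,b term ids (vectors are paired elementwise).
#' @return numeric distance(s); `Inf` marks unreachable pairs.
#' @export
ontologyDistance <- function(graph, a, b) {
  ia <- .termIndex(graph, a); ib <- .termIndex(graph, b)
  stopifnot(length(ia) == length(ib))
  ua <- unique(ia)
  d <- igraph::distances(graph@graph, v = ua, mode = "all")
  out <- d[cbind(match(ia, ua), ib)]
  as.numeric(out)
}

#' Random-pair ontology distance baseline
#'
#' Distances between `n` pairs of terms sampled uniformly with replacement,
#' the null profile an informative matcher's prediction-to-truth distances
#' are compared against.
#'
#' @param graph an [OntologyGraph-class].
#' @param n number of pairs (>= 1).
#' @param seed integer seed; the draw is reproducible.
#' @return numeric vector of `n` distances.
#' @export
randomDistanceBaseline <- function(graph, n, seed = 1L) {
  if (length(graph@termIds) == 0)
    glStop("cannot sample distances from an empty ontology",
           "geolabel_obo_error")
  stopifnot(n >= 1)
  idx <- withSeed(seed, sample.int(length(graph@termIds), 2L * n,
                                   replace = TRUE))
  ontologyDistance(graph, graph@termIds[idx[seq_len(n)]],
                   graph@termIds[idx[n + seq_len(n)]])
}

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## .Random.seed (all package randomness flows through this).
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
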