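## Shared fixtures, built in code.

fixtureOntology <- function() {
  loadOBO(system.file("extdata", "toy_tissues_synthetic.obo",
                      package = "geolabel"))
}

## Table-1-style record: a mouse pancreas sample with a rich
## Characteristics block.
fixturePancreasSample <- function() {
  sampleMetadata(
    "GSM17122", seriesId = "GSE1000", organism = "Mus musculus",
    characteristics = c(`1` = paste(
      "Genetic Background: NOD",
      "Transgene: BDC2.5 T cell receptor genes",
      "Age: 25 days", "Tissue: Pancreas",
      "Isolation: FACS on CD45+ Hoechst- (viable) cells", sep = "; ")))
}

## Independent BFS over an adjacency list; used as the oracle for depths
## and distances (never touches the package's igraph machinery).
bfsDistances <- function(adj, start) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[start] <- 0
  queue <- start
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (v in adj[[u]]) {
      if (is.infinite(dist[v])) {
        dist[v] <- dist[u] + 1
        queue <- c(queue, v)
      }
    }
  }
  dist
}

## undirected adjacency list of an OntologyGraph, built from the parents
## slot only
undirectedAdj <- function(graph) {
  ids <- termIds(graph)
  adj <- stats::setNames(rep(list(character()), length(ids)), ids)
  for (i in seq_along(ids)) {
    for (p in graph@parents[[i]]) {
      adj[[ids[i]]] <- c(adj[[ids[i]]], p)
      adj[[p]] <- c(adj[[p]], ids[i])
    }
  }
  adj
}

## directed child->parent adjacency
upwardAdj <- function(graph) {
  ids <- termIds(graph)
  stats::setNames(graph@parents, ids)
}

## naive multi-pattern scan: every (pattern, position) pair, substring
## comparison only — the brute-force oracle for the automaton
naiveScan <- function(patterns, text, caseInsensitive = TRUE) {
  if (caseInsensitive) { text <- tolower(text) }
  hits <- list()
  for (p in patterns) {
    pp <- if (caseInsensitive) tolower(p) else p
    np <- nchar(pp)
    if (np > nchar(text)) next
    for (s in seq_len(nchar(text) - np + 1L)) {
      if (substr(text, s, s + np - 1L) == pp)
        hits[[length(hits) + 1L]] <- data.frame(
          pattern = pp, start = s, end = s + np - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(pattern = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out[order(out$pattern, out$start), , drop = FALSE]
}

## small labeled expression toy: 2 classes x nPer samples, nGenes genes,
## first informative gene separates the classes
toyExpression <- function(nPer = 10, nGenes = 12, shift = 3, seed = 42,
                          nSeries = 4) {
  withSeed(seed, {
    n <- 2 * nPer
    cls <- rep(c("A", "B"), each = nPer)
    v <- matrix(rnorm(nGenes * n, 7, 1), nGenes, n)
    v[1, cls == "B"] <- v[1, cls == "B"] + shift
    v[2, cls == "B"] <- v[2, cls == "B"] + shift
    rownames(v) <- sprintf("G%03d", seq_len(nGenes))
    colnames(v) <- sprintf("S%03d", seq_len(n))
    se <- expressionMatrix(v, seriesIds = rep_len(
      sprintf("GSE%d", seq_len(nSeries)), n), isGeneLevel = TRUE)
    list(se = se, labels = stats::setNames(cls, colnames(v)))
  })
}

withSeed <- geolabel:::withSeed
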