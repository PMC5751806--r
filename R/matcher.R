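#' Tissue dictionary matcher configuration
#'
#' Knobs guarding against false positives from short or generic ontology
#' synonyms ("bud", "cap", ...): matching is case-insensitive by default,
#' matches must be delimited by non-alphanumeric characters (so "cap" does
#' not fire inside "capsule"), patterns shorter than `minPatternLength`
#' characters are not indexed, and an explicit stoplist of surface strings
#' can be supplied.
#'
#' @param caseInsensitive lowercase patterns and text before matching.
#' @param requireTokenBoundaries keep only matches whose flanking characters
#'   are non-alphanumeric (or text boundaries).
#' @param minPatternLength minimum pattern length in characters (>= 1).
#' @param stoplist character vector of surface strings never indexed.
#' @return a list with class `"MatcherConfig"`.
#' @export
matcherConfig <- function(caseInsensitive = TRUE,
                          requireTokenBoundaries = TRUE,
                          minPatternLength = 3L,
                          stoplist = character()) {
  stopifnot(minPatternLength >= 1)
  structure(list(caseInsensitive = caseInsensitive,
                 requireTokenBoundaries = requireTokenBoundaries,
                 minPatternLength = as.integer(minPatternLength),
                 stoplist = stoplist),
            class = "MatcherConfig")
}

#' TissueMatcher: an Aho-Corasick automaton over ontology surface strings
#'
#' Built by [buildMatcher()]; one pass over a text yields every occurrence
#' of every indexed term name or synonym.
#'
#' @slot patterns indexed surface strings (normalized).
#' @slot patternTerms list mapping each pattern to the term id(s) it names
#'   (a shared surface string maps to all of them).
#' @slot patternScopes list of provenance strings (`"name"` or the synonym
#'   scope) parallel to `patternTerms`.
#' @slot kids,fail,out the automaton: per-node child maps (named integer
#'   vectors), failure links, and output pattern indices.
#' @slot config the [matcherConfig()] used.
#' @export
setClass("TissueMatcher",
  representation(patterns = "character", patternTerms = "list",
                 patternScopes = "list", kids = "list", fail = "integer",
                 out = "list", config = "list"))

setMethod("show", "TissueMatcher", function(object) {
  cat("TissueMatcher:", length(object@patterns), "patterns,",
      length(object@kids), "automaton states\n")
  invisible(object)
})

#' Build the tissue term matcher
#'
#' Indexes the primary name and every synonym (all OBO scopes; the scope is
#' recorded for provenance) of every non-obsolete term, subject to the
#' [matcherConfig()] length and stoplist filters, into an Aho-Corasick
#' automaton. A surface string shared by several terms maps to all of them;
#' the ambiguity is resolved at selection time ([matchTissue()]).
#'
#' @param graph an [OntologyGraph-class].
#' @param cfg a [matcherConfig()].
#' @return a [TissueMatcher-class].
#' @export
buildMatcher <- function(graph, cfg = matcherConfig()) {
  pats <- character(); terms <- list(); scopes <- list()
  norm <- function(s) if (cfg$caseInsensitive) tolower(s) else s
  stop_ <- norm(cfg$stoplist)
  addPattern <- function(surface, termId, scope) {
    s <- norm(trimws(surface))
    if (nchar(s) < cfg$minPatternLength || s %in% stop_ || !nzchar(s))
      return()
    i <- match(s, pats)
    if (is.na(i)) {
      pats <<- c(pats, s)
      terms[[length(pats)]] <<- termId
      scopes[[length(pats)]] <<- scope
    } else if (!termId %in% terms[[i]]) {
      terms[[i]] <<- c(terms[[i]], termId)
      scopes[[i]] <<- c(scopes[[i]], scope)
    }
  }
  for (i in seq_along(graph@termIds)) {
    if (graph@obsolete[i]) next
    addPattern(graph@termNames[i], graph@termIds[i], "name")
    syn <- graph@synonyms[[i]]
    for (j in seq_len(nrow(syn)))
      addPattern(syn$text[j], graph@termIds[i], syn$scope[j])
  }
  auto <- buildAutomaton(pats)
  new("TissueMatcher", patterns = pats, patternTerms = terms,
      patternScopes = scopes, kids = auto$kids, fail = auto$fail,
      out = auto$out, config = unclass(cfg))
}

## Classic Aho-Corasick construction: trie insertion then BFS failure links;
## each node's output set inherits its failure node's outputs.
buildAutomaton <- function(patterns) {
  kids <- list(integer())   # node 1 = root
  out <- list(integer())
  for (p in seq_along(patterns)) {
    chars <- strsplit(patterns[p], "", fixed = TRUE)[[1]]
    cur <- 1L
    for (ch in chars) {
      nxt <- kids[[cur]][ch]
      if (is.na(nxt)) {
        kids[[length(kids) + 1L]] <- integer()
        out[[length(kids)]] <- integer()
        nxt <- length(kids)
        kids[[cur]][ch] <- nxt
      }
      cur <- as.integer(nxt)
    }
    out[[cur]] <- c(out[[cur]], p)
  }
  fail <- rep(1L, length(kids))
  queue <- as.integer(kids[[1L]])
  while (length(queue)) {
    u <- queue[1L]; queue <- queue[-1L]
    for (ch in names(kids[[u]])) {
      v <- as.integer(kids[[u]][ch])
      f <- fail[u]
      while (f != 1L && is.na(kids[[f]][ch])) f <- fail[f]
      cand <- kids[[f]][ch]
      fail[v] <- if (!is.na(cand) && as.integer(cand) != v)
        as.integer(cand) else 1L
      out[[v]] <- c(out[[v]], out[[fail[v]]])
      queue <- c(queue, v)
    }
  }
  list(kids = kids, fail = fail, out = out)
}

#' Find all ontology term occurrences in a text
#'
#' One pass of the automaton over `text`; every occurrence of every indexed
#' pattern is reported (expanded per term for shared surface strings), then
#' filtered by the token-boundary rule if configured.
#'
#' @param matcher a [TissueMatcher-class].
#' @param text a single string.
#' @return data frame with columns `pattern`, `termId`, `scope`, `start`,
#'   `end` (1-based character positions in `text`); zero rows when nothing
#'   matches.
#' @export
findMatches <- function(matcher, text) {
  empty <- data.frame(pattern = character(), termId = character(),
                      scope = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(text) || !length(matcher@patterns))
    return(empty)
  scanText <- if (matcher@config$caseInsensitive) tolower(text) else text
  chars <- strsplit(scanText, "", fixed = TRUE)[[1]]
  kids <- matcher@kids; fail <- matcher@fail; out <- matcher@out
  hitPat <- integer(); hitEnd <- integer()
  cur <- 1L
  for (i in seq_along(chars)) {
    ch <- chars[i]
    while (cur != 1L && is.na(kids[[cur]][ch])) cur <- fail[cur]
    nxt <- kids[[cur]][ch]
    cur <- if (!is.na(nxt)) as.integer(nxt) else 1L
    for (p in out[[cur]]) {
      hitPat <- c(hitPat, p); hitEnd <- c(hitEnd, i)
    }
  }
  if (!length(hitPat)) return(empty)
  plen <- nchar(matcher@patterns[hitPat])
  start <- hitEnd - plen + 1L
  keep <- rep(TRUE, length(hitPat))
  if (matcher@config$requireTokenBoundaries) {
    isAlnum <- grepl("[[:alnum:]]", chars)
    keep <- (start == 1L | !isAlnum[pmax(start - 1L, 1L)]) &
            (hitEnd == length(chars) |
             !isAlnum[pmin(hitEnd + 1L, length(chars))])
  }
  if (!any(keep)) return(empty)
  rows <- lapply(which(keep), function(h) {
    p <- hitPat[h]
    data.frame(pattern = matcher@patterns[p],
               termId = matcher@patternTerms[[p]],
               scope = matcher@patternScopes[[p]],
               start = start[h], end = hitEnd[h],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Map a sample's metadata to a tissue ontology term
#'
#' Fields are searched in the canonical order; within Characteristics, pairs
#' whose key names the tissue (`tissue`, `organ`, `cell type`, `source`) are
#' inspected before the remaining pairs. The first field group yielding any
#' hit ends the search. Among that group's hits the *shallowest* (most
#' general) term is selected; ties are broken by the longer matched surface
#' string, then the lexicographically smallest term id — a deterministic,
#' precision-first rule.
#'
#' @param meta a [SampleMetadata-class].
#' @param order a [fieldOrder()].
#' @param matcher a [TissueMatcher-class] built from `graph`.
#' @param graph the [OntologyGraph-class] the matcher indexes.
#' @return a `TissueLabel` (see [SampleLabel-class]) or `NULL`.
#' @export
matchTissue <- function(meta, order = fieldOrder(), matcher, graph) {
  keyRe <- "(tissue|organ|cell[ _-]?type|source)"
  for (fieldClass in order) {
    entries <- fieldTexts(meta, fieldClass, keyPattern = keyRe)
    if (!length(entries)) next
    keyed <- vapply(entries, function(e)
      !is.na(e$key) && grepl(keyRe, e$key, ignore.case = TRUE), TRUE)
    for (group in list(entries[keyed], entries[!keyed])) {
      if (!length(group)) next
      hits <- do.call(rbind, lapply(group, function(e) {
        text <- if (!is.na(e$key) && nzchar(e$key))
          paste0(e$key, ": ", e$value) else e$value
        h <- findMatches(matcher, text)
        if (nrow(h)) {
          h$field <- e$field
          h$surface <- substr(rep(text, nrow(h)), h$start, h$end)
        }
        h
      }))
      if (is.null(hits) || !nrow(hits)) next
      hits$depth <- termDepth(graph, hits$termId)
      ord <- order(hits$depth, -nchar(hits$surface), hits$termId)
      best <- hits[ord[1L], ]
      return(new("TissueLabel", sampleId = meta@sampleId,
                 termId = best$termId,
                 termName = termNames(graph)[[best$termId]],
                 depth = as.integer(best$depth), source = "text",
                 matchedField = best$field, matchedText = best$surface,
                 confidence = 1))
    }
  }
  NULL
}
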