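#' Read a Gene Ontology DAG from an OBO file
#'
#' A minimal OBO 1.2 reader covering what level standardization needs:
#' `[Term]` stanzas with `id`, `name`, `namespace`, `is_a` parents and
#' `is_obsolete`. Only `is_a` edges are kept (`part_of` and other
#' relationships are ignored). Term depth is the length of the shortest
#' `is_a` path to the namespace root.
#'
#' @param path path to the `.obo` file.
#' @return An object of class `dw_go_dag`: list with `parents` (named list,
#'   term -> is_a parents), `namespace`, `obsolete` (character vector) and
#'   `depth` (named integer vector, roots at 0).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  parents <- list()
  namespace <- character(0)
  obsolete <- character(0)
  cur <- NULL; cur_parents <- character(0); cur_ns <- NA_character_
  cur_obs <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur)) {
      parents[[cur]] <<- cur_parents
      namespace[cur] <<- cur_ns
      if (cur_obs) obsolete <<- c(obsolete, cur)
    }
  }
  for (ln in lines) {
    ln <- trimws(sub("!.*$", "", ln))
    if (ln == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- NULL; cur_parents <- character(0); cur_ns <- NA_character_
      cur_obs <- FALSE
    } else if (grepl("^\\[", ln)) {
      flush()
      in_term <- FALSE
      cur <- NULL
    } else if (in_term && nzchar(ln)) {
      if (startsWith(ln, "id:")) {
        cur <- trimws(sub("^id:", "", ln))
      } else if (startsWith(ln, "is_a:")) {
        cur_parents <- c(cur_parents,
                         trimws(strsplit(sub("^is_a:", "", ln), " ")[[1]][2]))
      } else if (startsWith(ln, "namespace:")) {
        cur_ns <- trimws(sub("^namespace:", "", ln))
      } else if (startsWith(ln, "is_obsolete:")) {
        cur_obs <- grepl("true", ln, fixed = TRUE)
      }
    }
  }
  flush()
  terms <- names(parents)
  parents <- lapply(parents, function(p) intersect(p, terms))
  # children map, then BFS from the roots for shortest-path depths
  depth <- stats::setNames(rep(NA_integer_, length(terms)), terms)
  live <- setdiff(terms, obsolete)
  children <- list()
  for (tm in live) {
    for (p in parents[[tm]]) children[[p]] <- c(children[[p]], tm)
  }
  frontier <- live[lengths(parents[live]) == 0L]
  depth[frontier] <- 0L
  lvl <- 0L
  while (length(frontier) > 0L) {
    nxt <- setdiff(unique(unlist(children[frontier], use.names = FALSE)),
                   names(depth)[!is.na(depth)])
    depth[nxt] <- lvl + 1L
    frontier <- nxt
    lvl <- lvl + 1L
  }
  structure(list(parents = parents, namespace = namespace,
                 obsolete = obsolete, depth = depth),
            class = "dw_go_dag")
}

#' @export
print.dw_go_dag <- function(x, ...) {
  cat(sprintf("<dw_go_dag> %d terms (%d obsolete), max depth %d\n",
              length(x$parents), length(x$obsolete),
              suppressWarnings(max(x$depth, na.rm = TRUE))))
  invisible(x)
}

#' Read gene-to-GO annotations from a two-column TSV
#'
#' Lines are `gene<TAB>GO:NNNNNNN`; `#` comments allowed.
#'
#' @param path path to the annotation file.
#' @return Named list, gene -> character vector of term ids.
#' @export
read_go_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    dw_stop(sprintf("malformed annotation line in '%s'", path),
            "dw_parse_error")
  }
  genes <- vapply(fields, `[[`, "", 1L)
  terms <- vapply(fields, `[[`, "", 2L)
  tapply(terms, genes, as_set, simplify = FALSE)[unique(genes)]
}

# all is_a ancestors of a term (excluding itself), memoized in `env`
go_ancestors <- function(dag, term, env) {
  memo <- env[[term]]
  if (!is.null(memo)) return(memo)
  ps <- dag$parents[[term]]
  anc <- ps
  for (p in ps) anc <- union(anc, go_ancestors(dag, p, env))
  env[[term]] <- anc
  anc
}

#' Standardize GO annotations to a fixed level of the hierarchy
#'
#' Terms sitting exactly at the requested depth are kept; deeper terms are
#' replaced by all of their ancestors at that depth; terms above the level
#' are dropped, as are obsolete terms and terms absent from the DAG (with a
#' warning). Depth is the shortest is_a path from the namespace root.
#' Idempotent at a fixed level.
#'
#' @param dag a [read_obo()] DAG.
#' @param raw_annotations named list, gene -> character vector of term ids.
#' @param level target depth (default 5).
#' @return An object of class `dw_go_map`: list with `terms_by_gene` (gene ->
#'   standardized term set) and `level`.
#' @export
standardize_go <- function(dag, raw_annotations, level = 5L) {
  dw_assert(level >= 1, "level must be at least 1")
  env <- new.env(parent = emptyenv())
  known <- names(dag$parents)
  missing_terms <- character(0)
  std_one <- function(term) {
    if (!(term %in% known)) {
      missing_terms <<- c(missing_terms, term)
      return(character(0))
    }
    if (term %in% dag$obsolete) return(character(0))
    d <- dag$depth[[term]]
    if (is.na(d) || d < level) return(character(0))
    if (d == level) return(term)
    anc <- go_ancestors(dag, term, env)
    anc[!is.na(dag$depth[anc]) & dag$depth[anc] == level]
  }
  out <- lapply(raw_annotations, function(terms) {
    as_set(unlist(lapply(terms, std_one), use.names = FALSE))
  })
  if (length(missing_terms) > 0L) {
    warning("dropped term(s) absent from the DAG: ",
            paste(unique(missing_terms), collapse = ", "))
  }
  structure(list(terms_by_gene = out, level = as.integer(level)),
            class = "dw_go_map")
}
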