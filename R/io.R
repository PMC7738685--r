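#' Read a PPI network from a tab-separated edge list
#'
#' Expects lines of the form `geneA<TAB>geneB[<TAB>confidence]`; lines
#' starting with `#` are comments. Self-loops and duplicate edges are
#' dropped, and when a confidence threshold is given, edges with confidence
#' strictly below it are removed before the graph is built. Isolated nodes
#' (nodes left without any edge) are dropped.
#'
#' @param path path to the edge-list file.
#' @param confidence_threshold optional value in `[0, 1]`; edges with
#'   confidence `< threshold` are filtered out. Requires a third column;
#'   edges missing a confidence value are dropped with a warning.
#' @return A [ppi_network].
#' @export
read_network <- function(path, confidence_threshold = NULL) {
  if (!is.null(confidence_threshold)) {
    dw_assert(confidence_threshold >= 0 && confidence_threshold <= 1,
              "confidence_threshold must lie in [0, 1]")
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("empty network file: '", path, "'")
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          nodes = character(0), adj = list(),
                          confidence = NULL),
                     class = "ppi_network"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    dw_stop(sprintf("malformed network line %d in '%s': fewer than 2 fields",
                    line_no[which(nf < 2L)[1]], path), "dw_parse_error")
  }
  a <- vapply(fields, `[[`, "", 1L)
  b <- vapply(fields, `[[`, "", 2L)
  has_conf <- nf >= 3L
  conf <- rep(NA_real_, length(lines))
  conf[has_conf] <- suppressWarnings(
    as.numeric(vapply(fields[has_conf], `[[`, "", 3L)))
  if (any(has_conf & is.na(conf))) {
    dw_stop(sprintf("malformed network line %d in '%s': non-numeric confidence",
                    line_no[which(has_conf & is.na(conf))[1]], path),
            "dw_parse_error")
  }
  if (!is.null(confidence_threshold)) {
    if (!any(has_conf)) {
      dw_stop("confidence_threshold given but the file has no confidence column",
              "dw_config_error")
    }
    if (any(!has_conf)) {
      warning(sum(!has_conf),
              " edge(s) without a confidence value dropped under threshold filtering")
    }
    keep_e <- has_conf & conf >= confidence_threshold
    a <- a[keep_e]; b <- b[keep_e]; conf <- conf[keep_e]
    has_conf <- rep(TRUE, length(a))
  }
  if (length(a) == 0L) {
    warning("no edges survive the confidence filter in '", path, "'")
    return(structure(list(graph = igraph::make_empty_graph(directed = FALSE),
                          nodes = character(0), adj = list(),
                          confidence = NULL),
                     class = "ppi_network"))
  }
  ppi_network(cbind(a, b), confidence = if (all(has_conf)) conf else NULL)
}

#' Read a binary somatic mutation profile
#'
#' Two dialects are supported and yield identical profiles on equivalent
#' content: `gene_major` lines are `GENE<TAB>s1,s2,...` (comma-joined sample
#' ids) and `sample_major` lines are `SAMPLE<TAB>g1<TAB>g2...`. Duplicate
#' gene lines in `gene_major` are unioned with a warning. The sample
#' universe is the union of all sample ids observed in the file.
#'
#' @param path path to the mutation file.
#' @param dialect `"gene_major"` or `"sample_major"`.
#' @return A [mutation_profile].
#' @export
read_mutations <- function(path, dialect = c("gene_major", "sample_major")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    dw_stop(sprintf("empty mutation file: '%s'", path), "dw_parse_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    dw_stop(sprintf("malformed mutation line %d in '%s': fewer than 2 fields",
                    line_no[which(lengths(fields) < 2L)[1]], path),
            "dw_parse_error")
  }
  sets <- list()
  if (dialect == "gene_major") {
    genes <- vapply(fields, `[[`, "", 1L)
    samples <- lapply(fields, function(f) {
      s <- unlist(strsplit(f[2], ",", fixed = TRUE))
      s[nzchar(s)]
    })
    if (anyDuplicated(genes)) {
      warning("duplicate gene lines in '", path, "' unioned: ",
              paste(unique(genes[duplicated(genes)]), collapse = ", "))
    }
    sets <- tapply(samples, genes, function(x) as_set(unlist(x)),
                   simplify = FALSE)
    sets <- sets[unique(genes)]
  } else {
    for (f in fields) {
      smp <- f[1]
      for (g in f[-1]) {
        if (!nzchar(g)) next
        sets[[g]] <- c(sets[[g]], smp)
      }
    }
    sets <- lapply(sets, as_set)
  }
  mutation_profile(sets)
}

#' Write a mutation profile
#'
#' Serializes to either mutation dialect; `read_mutations()` on the result
#' reproduces the profile (up to the sample universe, which on reading is
#' the set of observed samples).
#'
#' @param profile a [mutation_profile].
#' @param path output path.
#' @param dialect output dialect, as in [read_mutations()].
#' @export
write_mutations <- function(profile, path,
                            dialect = c("gene_major", "sample_major")) {
  dialect <- match.arg(dialect)
  if (dialect == "gene_major") {
    genes <- names(profile$samples_by_gene)
    lines <- vapply(genes, function(g) {
      paste0(g, "\t", paste(profile$samples_by_gene[[g]], collapse = ","))
    }, "")
  } else {
    by_sample <- list()
    for (g in names(profile$samples_by_gene)) {
      for (s in profile$samples_by_gene[[g]]) {
        by_sample[[s]] <- c(by_sample[[s]], g)
      }
    }
    lines <- vapply(names(by_sample), function(s) {
      paste(c(s, as_set(by_sample[[s]])), collapse = "\t")
    }, "")
  }
  dw_write_atomic(lines, path)
}

#' Drop genes mutated in less than a given fraction of the cohort
#'
#' A gene is removed when its mutated-sample count is strictly below
#' `min_fraction * |sample universe|` (no rounding of the threshold). The
#' sample universe is unchanged. Idempotent.
#'
#' @param profile a [mutation_profile].
#' @param min_fraction fraction of the cohort in `[0, 1]` (default 0.01).
#' @return The filtered [mutation_profile].
#' @export
filter_low_frequency_genes <- function(profile, min_fraction = 0.01) {
  dw_assert(min_fraction >= 0 && min_fraction <= 1,
            "min_fraction must lie in [0, 1]")
  cutoff <- min_fraction * length(profile$sample_universe)
  keep <- vapply(profile$samples_by_gene, function(s) length(s) >= cutoff,
                 logical(1))
  mutation_profile(profile$samples_by_gene[keep], profile$sample_universe)
}

#' Read a reference pathway collection in GMT format
#'
#' Standard GMT: one pathway per line, `name<TAB>description<TAB>gene...`.
#' When `restrict_to` is given, each pathway is first intersected with that
#' gene list (e.g. known cancer genes) and then pathways smaller than
#' `min_size` are dropped. Original order is preserved.
#'
#' @param path path to the `.gmt` file.
#' @param restrict_to optional character vector of genes to intersect each
#'   pathway with before size filtering.
#' @param min_size minimum pathway size after restriction (default 1).
#' @return Named list of gene sets (class `dw_pathways`), with attribute
#'   `provenance` set to the file path.
#' @export
read_gmt <- function(path, restrict_to = NULL, min_size = 1L) {
  lines <- readLines(path)
  nonblank <- which(nzchar(trimws(lines)))
  bad <- nonblank[lengths(strsplit(lines[nonblank], "\t", fixed = TRUE)) < 3L]
  if (length(bad)) {
    dw_stop(sprintf("malformed GMT line %d in '%s': fewer than 3 fields",
                    bad[1], path), "dw_parse_error")
  }
  pw <- fgsea::gmtPathways(path)
  pw <- lapply(pw, as_set)
  if (!is.null(restrict_to)) {
    restrict_to <- as_set(restrict_to)
    pw <- lapply(pw, intersect, y = restrict_to)
  }
  pw <- pw[lengths(pw) >= min_size]
  structure(pw, class = "dw_pathways", provenance = path)
}

#' Read a plain-text gene list (one symbol per line)
#'
#' @param path path to the file; `#` comments and blank lines are skipped.
#' @return Character vector of unique gene symbols in file order.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  unique(lines)
}

#' Write a discovered module set with its scores
#'
#' Produces a TSV with columns `rank`, `MS`, `COV`, `MEX`, `size`, `genes`
#' (comma-joined), one row per module in rank order.
#'
#' @param modules a [dw_module_set].
#' @param scores data.frame with columns `cov`, `mex`, `ms` aligned with the
#'   modules (as returned by discovery), or `NULL` to recompute nothing and
#'   write NA scores.
#' @param path output path.
#' @export
write_modules <- function(modules, scores, path) {
  n <- length(modules$modules)
  if (!is.null(scores)) {
    dw_assert(nrow(scores) == n, "scores must align with modules",
              "dw_data_error")
  } else {
    scores <- data.frame(cov = rep(NA_real_, n), mex = rep(NA_real_, n),
                         ms = rep(NA_real_, n))
  }
  header <- "rank\tMS\tCOV\tMEX\tsize\tgenes"
  rows <- character(n)
  for (i in seq_len(n)) {
    m <- modules$modules[[i]]
    rows[i] <- sprintf("%d\t%.17g\t%.17g\t%.17g\t%d\t%s",
                       i, scores$ms[i], scores$cov[i], scores$mex[i],
                       length(m$genes), paste(m$genes, collapse = ","))
  }
  dw_write_atomic(c(header, rows), path)
}

#' Read a module table written by [write_modules()]
#'
#' @param path path to the TSV.
#' @return List with `modules` (a [dw_module_set]) and `scores` (data.frame
#'   with columns `cov`, `mex`, `ms`).
#' @export
read_modules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(list(modules = dw_module_set(),
                scores = data.frame(cov = numeric(0), mex = numeric(0),
                                    ms = numeric(0))))
  }
  df <- df[order(df$rank), , drop = FALSE]
  mods <- lapply(strsplit(df$genes, ",", fixed = TRUE), dw_module)
  list(modules = dw_module_set(mods),
       scores = data.frame(cov = df$COV, mex = df$MEX, ms = df$MS))
}

#' Write a PPI network as a tab-separated edge list
#'
#' @param network a [ppi_network].
#' @param path output path.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network$graph)
  flip <- el[, 1] > el[, 2]
  el[flip, ] <- el[flip, 2:1]
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  if (!is.null(network$confidence)) {
    key <- paste(el[, 1], el[, 2], sep = "\r")
    lines <- sprintf("%s\t%s\t%g", el[, 1], el[, 2],
                     network$confidence[key])
  } else {
    lines <- sprintf("%s\t%s", el[, 1], el[, 2])
  }
  dw_write_atomic(lines, path)
}

#' Write named gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled; default `"na"`).
#' @export
write_gmt <- function(sets, path, description = "na") {
  nm <- names(sets)
  dw_assert(!is.null(nm) && all(nzchar(nm)), "gene sets must be named")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(nm[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  dw_write_atomic(lines, path)
}
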