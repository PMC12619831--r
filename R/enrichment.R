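#' Over-representation analysis of a selected metabolite list
#'
#' One-sided hypergeometric (upper-tail) test of each metabolite set against
#' the selected list, within the given universe. Each set is intersected
#' with the universe before testing; the enrichment ratio is
#' observed / expected hits = `n_hits / (n_selected * set_size /
#' universe_size)`. Benjamini-Hochberg q-values are computed across sets.
#'
#' @param selected character vector of selected metabolite ids (must be a
#'   subset of `universe`).
#' @param sets list of metabolite sets as returned by [read_gmt()], or a
#'   named list of character vectors.
#' @param universe character vector of all testable metabolite ids
#'   (typically the metabolites surviving preprocessing).
#' @return data.frame sorted by p-value with set_id, name, n_hits,
#'   n_selected, set_size, universe_size, enrichment_ratio, p_value,
#'   q_value.
#' @export
ora <- function(selected, sets, universe) {
  selected <- unique(as.character(selected))
  universe <- unique(as.character(universe))
  if (length(selected) == 0L) stop("'selected' must be nonempty")
  if (length(universe) == 0L) stop("'universe' must be nonempty")
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    stop("selected metabolites outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  }
  sets <- .normalize_sets(sets)
  rows <- lapply(names(sets), function(sid) {
    s <- sets[[sid]]
    members <- intersect(unique(s$members), universe)
    m <- length(members)
    if (m == 0L) return(NULL)
    hits <- length(intersect(selected, members))
    k <- length(selected); N <- length(universe)
    expected <- k * m / N
    data.frame(set_id = sid, name = s$name,
               n_hits = hits, n_selected = k, set_size = m,
               universe_size = N,
               enrichment_ratio = hits / expected,
               p_value = stats::phyper(hits - 1, m, N - m, k,
                                       lower.tail = FALSE),
               row.names = NULL)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) stop("no set overlaps the universe")
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out[order(out$p_value), , drop = FALSE]
}

# Internal: accept read_gmt() output or a plain named list of id vectors.
.normalize_sets <- function(sets) {
  if (length(sets) == 0L) stop("no metabolite sets supplied")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  lapply(sets, function(s) {
    if (is.list(s) && !is.null(s$members)) {
      list(name = if (is.null(s$name)) "" else s$name,
           members = as.character(s$members))
    } else {
      list(name = "", members = as.character(s))
    }
  })
}

#' Read metabolite sets from a GMT file
#'
#' Tab-separated, one set per line: set id, description, then member ids.
#' Both LF and CRLF line endings are accepted. Duplicate members within a
#' set are removed with a warning.
#'
#' @param path path to a `.gmt` file.
#' @return named list of sets, each `list(name, members)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    }
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    sets[[f[1]]] <- list(name = f[2], members = members)
  }
  sets
}

#' Write metabolite sets to a GMT file
#'
#' @param sets named list of sets (`list(name, members)` or character
#'   vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  sets <- .normalize_sets(sets)
  lines <- vapply(names(sets), function(sid) {
    paste(c(sid, sets[[sid]]$name, sets[[sid]]$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
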