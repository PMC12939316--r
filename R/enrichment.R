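#' Build a miRNA -> target map
#'
#' @param targets Named list, canonical miRNA display name -> character
#'   vector of gene symbols.
#' @param universe Background gene universe; defaults to the union of all
#'   target sets.
#' @return A `target_map` (named list with a `universe` attribute).
#' @export
target_map <- function(targets, universe = NULL) {
  stopifnot(is.list(targets), length(targets) > 0L,
            !is.null(names(targets)), all(nzchar(names(targets))))
  targets <- lapply(targets, function(x) sort(unique(as.character(x))))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(targets, use.names = FALSE)))
  } else {
    universe <- sort(unique(as.character(universe)))
    stray <- setdiff(unlist(targets, use.names = FALSE), universe)
    if (length(stray) > 0L) {
      stop("target(s) outside the declared universe: ",
           paste(head(stray, 5), collapse = ", "), call. = FALSE)
    }
  }
  attr(targets, "universe") <- universe
  class(targets) <- "target_map"
  targets
}

#' Read a two-column miRNA/target TSV
#'
#' Columns `mirna` and `gene`; repeated rows are deduplicated; miRNA names
#' are canonicalized.
#'
#' @param path File path.
#' @return A `target_map`.
#' @export
read_target_map <- function(path) {
  df <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  stopifnot(all(c("mirna", "gene") %in% names(df)))
  df$mirna <- canonical_names(df$mirna)
  target_map(split(df$gene, df$mirna))
}

#' Write a target map as TSV
#'
#' @param map A `target_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_map <- function(map, path) {
  df <- tibble::tibble(
    mirna = rep(names(map), lengths(map)),
    gene = unlist(map, use.names = FALSE)
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Targets held in common, in union, or exclusively
#'
#' `all`: intersection of the queried miRNAs' target sets. `any`: their
#' union. `exclusive`: the union minus every target of any *other* miRNA in
#' the map (genes hit only by the query).
#'
#' @param mirnas Character vector of canonical display names (non-empty).
#' @param map A `target_map`; every queried miRNA must have an entry.
#' @param mode `"all"`, `"any"` or `"exclusive"`.
#' @return Sorted character vector of gene symbols.
#' @export
common_targets <- function(mirnas, map, mode = c("all", "any", "exclusive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "target_map"))
  mirnas <- unique(as.character(mirnas))
  if (length(mirnas) == 0L) {
    stop("empty miRNA query", call. = FALSE)
  }
  absent <- setdiff(mirnas, names(map))
  if (length(absent) > 0L) {
    stop("no target entry for: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  sets <- map[mirnas]
  out <- switch(mode,
    all = Reduce(intersect, sets),
    any = unique(unlist(sets, use.names = FALSE)),
    exclusive = {
      others <- unlist(map[setdiff(names(map), mirnas)], use.names = FALSE)
      setdiff(unlist(sets, use.names = FALSE), others)
    }
  )
  sort(unique(out))
}

#' Per-gene coverage: how many miRNAs target each gene
#'
#' @param map A `target_map`.
#' @return Named integer vector (genes targeted by at least one miRNA).
#' @export
coverage_counts <- function(map) {
  stopifnot(inherits(map, "target_map"))
  genes <- unlist(map, use.names = FALSE)
  if (length(genes) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(genes)
  stats::setNames(as.integer(tab), names(tab))
}

#' Select the most broadly targeted genes
#'
#' Genes targeted by at least `min_mirnas` distinct miRNAs, sorted by
#' coverage (desc) then name (asc), truncated to `cap`. `fraction`
#' optionally replaces the absolute threshold by a top-fraction cut of the
#' covered genes (e.g. 0.2 keeps the top 20% most targeted).
#'
#' @param counts Named coverage vector from [coverage_counts()].
#' @param min_mirnas Minimum distinct targeting miRNAs (default 40).
#' @param cap Maximum genes returned (default 100).
#' @param fraction Optional top fraction in (0, 1]; overrides `min_mirnas`.
#' @return Ordered character vector of gene symbols.
#' @export
select_top_targeted <- function(counts, min_mirnas = 40, cap = 100,
                                fraction = NULL) {
  stopifnot(min_mirnas >= 1)
  if (length(counts) == 0L) {
    return(character(0))
  }
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  if (!is.null(fraction)) {
    stopifnot(fraction > 0, fraction <= 1)
    keep <- ceiling(fraction * length(counts))
  } else {
    keep <- sum(counts >= min_mirnas)
  }
  head(names(counts)[seq_len(keep)], cap)
}

#' Hypergeometric over-representation tail probability
#'
#' P(X >= x) when drawing `n` genes from a universe of `M` containing `K`
#' annotated successes, computed through the hypergeometric survival
#' function (numerically stable; exact for the universe sizes used here).
#'
#' @param x Observed overlap.
#' @param K Gene-set size within the universe.
#' @param n Query size.
#' @param M Universe size.
#' @return Upper-tail probability in (0, 1].
#' @examples
#' hypergeom_p(4, 4, 5, 10)  # 6/252
#' @export
hypergeom_p <- function(x, K, n, M) {
  if (any(c(x, K, n, M) < 0) || K > M || n > M || x > min(K, n)) {
    stop(sprintf("inconsistent counts: x=%s K=%s n=%s M=%s", x, K, n, M),
         call. = FALSE)
  }
  if (x == 0) {
    return(1)
  }
  stats::phyper(x - 1, K, M - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment, order-preserving with the input.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, each in (0, 1], monotone in the
#'   sense of the BH cumulative-min pass.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues > 0), all(pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Read a GMT gene-set collection
#'
#' Tab-separated: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list, set name -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) {
    stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(
    lapply(parts, function(p) unique(p[-(1:2)])),
    vapply(parts, `[[`, character(1), 1)
  )
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of gene vectors.
#' @param path Output path.
#' @param descriptions Optional per-set description strings.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(sets))
  }
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation in the query against the
#' universe (one-sided, upper tail). q-values are BH-adjusted across all
#' tested sets before any overlap filter is applied.
#'
#' @param query Character vector of query genes. Genes outside the
#'   universe are dropped with a warning giving their count.
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene universe (e.g. the target-map
#'   universe).
#' @param min_overlap Minimum overlap for a set to be reported (default 1).
#' @return Tibble `set_name`, `x`, `K`, `n`, `M`, `p`, `q`, sorted by `q`
#'   then `p`.
#' @export
run_ora <- function(query, sets, universe, min_overlap = 1) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop("empty universe", call. = FALSE)
  }
  query <- unique(as.character(query))
  if (length(query) == 0L) {
    stop("empty query", call. = FALSE)
  }
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0L) {
    warning(length(dropped), " query gene(s) outside the universe dropped",
            call. = FALSE)
    query <- intersect(query, universe)
    if (length(query) == 0L) {
      stop("no query gene lies in the universe", call. = FALSE)
    }
  }
  n <- length(query)
  M <- length(universe)
  rows <- purrr::imap(sets, function(members, name) {
    members <- intersect(unique(members), universe)
    x <- length(intersect(members, query))
    tibble::tibble(set_name = name, x = x, K = length(members), n = n, M = M,
                   p = hypergeom_p(x, length(members), n, M))
  })
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out <- out[out$x >= min_overlap, , drop = FALSE]
  dplyr::arrange(out, .data$q, .data$p, .data$set_name)
}
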