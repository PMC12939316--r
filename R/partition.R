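#' Shared versus product-selective miRNAs within a food type
#'
#' Given the per-product top-k sets of one food type, a miRNA is *shared*
#' when it appears in the top-k of at least two products, and *selective*
#' for the single product whose top-k it appears in otherwise.
#'
#' @param top_sets Named list, product id -> character vector of canonical
#'   display names (a product's consensus top-k).
#' @return List with `shared` (sorted character vector) and `selective`
#'   (named list, product -> sorted character vector).
#' @export
shared_selective <- function(top_sets) {
  if (length(top_sets) == 0L) {
    stop("at least one product required", call. = FALSE)
  }
  top_sets <- lapply(top_sets, function(x) unique(as.character(x)))
  counts <- table(unlist(top_sets, use.names = FALSE))
  shared <- sort(names(counts)[counts >= 2])
  selective <- lapply(top_sets, function(x) sort(setdiff(x, shared)))
  list(shared = shared, selective = selective)
}

#' Partition presence-matrix rows into group-exclusive and shared sets
#'
#' A miRNA is exclusive to a food group when every one of its presence
#' cells — raw and processed states pooled — falls in that group;
#' otherwise it is shared across groups. The exclusive sets are pairwise
#' disjoint and, together with the shared set, cover every matrix row.
#'
#' @param matrix A `presence_matrix`.
#' @return An `exclusivity_partition`: list with `exclusive` (named list,
#'   group -> sorted names; every group of the matrix vocabulary present),
#'   `shared_multi_group` (sorted names) and `groups`.
#' @export
group_exclusive <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  groups <- attr(matrix, "groups") %||% unique(matrix$group)
  per_mirna <- split(matrix$group, matrix$mirna)
  n_groups <- vapply(per_mirna, function(g) length(unique(g)), integer(1))
  excl_names <- names(per_mirna)[n_groups == 1L]
  excl_group <- vapply(per_mirna[excl_names], function(g) g[1], character(1))
  exclusive <- lapply(stats::setNames(groups, groups), function(g) {
    sort(unname(excl_names[excl_group == g]))
  })
  out <- list(
    exclusive = exclusive,
    shared_multi_group = sort(names(per_mirna)[n_groups > 1L]),
    groups = groups
  )
  class(out) <- "exclusivity_partition"
  out
}

#' Group-exclusive miRNAs that persist after processing
#'
#' Members of any group's exclusive set that carry at least one
#' processed-state presence cell.
#'
#' @param partition An `exclusivity_partition` computed from `matrix`.
#' @param matrix The same `presence_matrix`.
#' @return Sorted character vector.
#' @export
processing_persistence <- function(partition, matrix) {
  stopifnot(inherits(partition, "exclusivity_partition"),
            inherits(matrix, "presence_matrix"))
  exclusives <- unlist(partition$exclusive, use.names = FALSE)
  processed <- unique(matrix$mirna[matrix$state == "processed"])
  sort(intersect(exclusives, processed))
}

#' Universe counts of a presence matrix
#'
#' @param matrix A `presence_matrix`.
#' @return List `n_raw`, `n_processed`, `n_union`: distinct canonical
#'   miRNAs with at least one raw cell, at least one processed cell, and
#'   overall.
#' @export
universe_counts <- function(matrix) {
  stopifnot(inherits(matrix, "presence_matrix"))
  list(
    n_raw = length(unique(matrix$mirna[matrix$state == "raw"])),
    n_processed = length(unique(matrix$mirna[matrix$state == "processed"])),
    n_union = length(unique(matrix$mirna))
  )
}

#' @export
print.exclusivity_partition <- function(x, ...) {
  cat("Exclusivity partition over", length(x$groups), "food groups\n")
  for (g in x$groups) {
    cat(sprintf("  %-12s %2d exclusive: %s\n", g, length(x$exclusive[[g]]),
                paste(x$exclusive[[g]], collapse = ", ")))
  }
  cat(sprintf("  shared across groups: %d\n", length(x$shared_multi_group)))
  invisible(x)
}

#' Serialize an exclusivity partition to JSON
#'
#' @param partition An `exclusivity_partition`.
#' @param persisted Optional persistence set to embed.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, persisted = NULL, path) {
  payload <- c(partition$exclusive,
               list(shared = partition$shared_multi_group))
  if (!is.null(persisted)) {
    payload$persisted <- persisted
  }
  jsonlite::write_json(payload, path, pretty = TRUE)
  invisible(path)
}
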