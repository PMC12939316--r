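#' Construct an interaction network
#'
#' Undirected simple graph over gene symbols with integer edge confidence
#' scores on the STRING 0-1000 scale. Self-loops are rejected; symmetric
#' duplicate pairs collapse to one edge keeping the maximum score.
#'
#' @param edges Data frame with columns `protein1`, `protein2`, `score`
#'   (integer 0-1000).
#' @param nodes Optional extra node names (isolated nodes allowed).
#' @return An `interaction_network`: list with `nodes` (sorted character)
#'   and `edges` (tibble with canonical `protein1 < protein2` ordering).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  stopifnot(all(c("protein1", "protein2", "score") %in% names(edges)))
  edges <- tibble::as_tibble(edges[, c("protein1", "protein2", "score")])
  if (any(edges$protein1 == edges$protein2)) {
    stop("self-loops are not allowed", call. = FALSE)
  }
  if (any(edges$score < 0 | edges$score > 1000)) {
    stop("edge scores must lie in [0, 1000]", call. = FALSE)
  }
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  edges$protein1 <- a
  edges$protein2 <- b
  if (nrow(edges) > 0L) {
    edges <- edges |>
      dplyr::group_by(.data$protein1, .data$protein2) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop") |>
      dplyr::arrange(.data$protein1, .data$protein2)
  }
  all_nodes <- sort(unique(c(edges$protein1, edges$protein2,
                             as.character(nodes))))
  out <- list(nodes = all_nodes, edges = edges)
  class(out) <- "interaction_network"
  out
}

#' Read a STRING-dialect edge list
#'
#' TSV with columns `protein1`, `protein2`, `combined_score`. Scores given
#' as fractions (values <= 1) are rescaled to the 0-1000 integer scale.
#' Self-loops are dropped with a warning giving their count; duplicate
#' pairs keep the maximum score.
#'
#' @param path File path.
#' @return An `interaction_network`.
#' @export
read_edges <- function(path) {
  df <- readr::read_tsv(path,
                        col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  required <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("edge file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score)) {
    bad <- which(is.na(score)) + 1L  # header offset
    stop("non-numeric combined_score at line(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  score <- ifelse(score <= 1, score * 1000, score)
  loops <- df$protein1 == df$protein2
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped", call. = FALSE)
  }
  interaction_network(tibble::tibble(
    protein1 = df$protein1[!loops],
    protein2 = df$protein2[!loops],
    score = as.integer(round(score[!loops]))
  ))
}

#' Write an edge list in the STRING dialect
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(net, path) {
  readr::write_tsv(
    tibble::tibble(protein1 = net$edges$protein1,
                   protein2 = net$edges$protein2,
                   combined_score = net$edges$score),
    path, progress = FALSE)
  invisible(path)
}

#' Threshold a network at a minimum confidence score
#'
#' Keeps edges with `score >= min_score`. Nodes are retained even when
#' they become isolated, so degree-0 entries stay visible.
#'
#' @param net An `interaction_network`.
#' @param min_score Integer in [0, 1000]; 700 is the usual
#'   "high confidence" cut.
#' @return A thresholded `interaction_network`.
#' @export
threshold <- function(net, min_score = 700) {
  stopifnot(inherits(net, "interaction_network"))
  if (min_score < 0 || min_score > 1000) {
    stop("min_score must lie in [0, 1000]", call. = FALSE)
  }
  kept <- net$edges[net$edges$score >= min_score, , drop = FALSE]
  interaction_network(kept, nodes = net$nodes)
}

#' Node degrees
#'
#' Number of distinct neighbors per node (isolated nodes report 0).
#'
#' @param net An `interaction_network`.
#' @return Named integer vector over all nodes, name-sorted.
#' @export
degrees <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  d <- stats::setNames(integer(length(net$nodes)), net$nodes)
  tab <- table(c(net$edges$protein1, net$edges$protein2))
  d[names(tab)] <- as.integer(tab)
  d
}

#' Filter nodes by minimum degree
#'
#' Entries with degree >= k, sorted by degree (desc) then name (asc) — the
#' presentation order of degree tables.
#'
#' @param degrees Named degree vector from [degrees()].
#' @param k Minimum degree (default 2).
#' @return Named integer vector.
#' @export
min_degree_filter <- function(degrees, k = 2) {
  stopifnot(k >= 0)
  kept <- degrees[degrees >= k]
  kept[order(-kept, names(kept))]
}

#' Hub nodes
#'
#' The highest-degree connected nodes, ties broken lexicographically.
#'
#' @param degrees Named degree vector.
#' @param top Number of hubs requested (default 5).
#' @return Character vector of at most `min(top, connected nodes)` names.
#' @export
hubs <- function(degrees, top = 5) {
  stopifnot(top >= 1)
  connected <- degrees[degrees > 0]
  connected <- connected[order(-connected, names(connected))]
  head(names(connected), top)
}
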