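#' Borda score of a rank position
#'
#' The frequency-weighted ordinal recurrence score assigns descending
#' scores to the top-N positions of a study's ranking: position 1 scores
#' `top_n`, position `top_n` scores 1, and positions beyond the window
#' score 0.
#'
#' @param position Integer vector of 1-based rank positions.
#' @param top_n Size of the scored window (default 10).
#' @return Numeric vector of scores.
#' @examples
#' borda_score(c(1, 10, 11), top_n = 10)  # 10, 1, 0
#' @export
borda_score <- function(position, top_n = 10) {
  stopifnot(all(position >= 1), top_n >= 1)
  pmax(top_n - position + 1, 0)
}

#' Score a tie group spanning contiguous positions
#'
#' Every member of a tie receives the arithmetic mean of the plain Borda
#' scores over the positions the tie spans; positions beyond the top-N
#' window contribute 0 to the mean, so total Borda mass is preserved.
#'
#' @param positions_spanned Contiguous integer positions occupied by the tie.
#' @param top_n Scored window size.
#' @return Single numeric score given to each tied member.
#' @examples
#' tie_scores(c(10, 11), top_n = 10)  # 0.5 each
#' @export
tie_scores <- function(positions_spanned, top_n = 10) {
  positions_spanned <- sort(as.integer(positions_spanned))
  if (length(positions_spanned) > 1L &&
      any(diff(positions_spanned) != 1L)) {
    stop("tie span must be contiguous: ",
         paste(positions_spanned, collapse = ","), call. = FALSE)
  }
  mean(borda_score(positions_spanned, top_n))
}

# Per-(study, product) scores for one ranking block. Tied rows share a
# printed rank and a tie token; the tie occupies the run of slots starting
# at that rank.
score_one_ranking <- function(df, top_n) {
  df <- df[order(df$position), , drop = FALSE]
  n <- nrow(df)
  # rows sharing a printed rank occupy the run of slots starting there;
  # untied rows keep their printed position (rank gaps stay gaps)
  offset <- stats::ave(rep(1L, n), df$position, FUN = seq_along) - 1L
  slot <- df$position + offset
  key <- ifelse(is.na(df$tie_group),
                sprintf("row%06d", seq_len(n)),
                paste(df$position, df$tie_group, sep = "\r"))
  score <- numeric(n)
  for (k in unique(key)) {
    idx <- which(key == k)
    score[idx] <- tie_scores(slot[idx], top_n)
  }
  df$score <- score
  df
}

#' Aggregate study rankings into Borda records
#'
#' Sums each miRNA's per-study Borda scores over every ranking whose
#' product belongs to the scope, counts in how many rankings it recurs,
#' and records its best (smallest) observed position. Product scope is a
#' single product; group scope is the same computation pooled over the
#' group's products. Studies have equal weight by default.
#'
#' @param rankings A `study_rankings` tibble (see [read_rankings()]).
#' @param scope_members Character vector of product ids in scope; default
#'   all products present.
#' @param weights Optional named numeric vector, study id -> weight
#'   (default 1 for every study).
#' @param top_n Scored window size; defaults to the `top_n` attribute of
#'   `rankings`, else 10.
#' @return Tibble of Borda records: `mirna`, `total_score`, `recurrence`,
#'   `best_position`.
#' @export
aggregate_scope <- function(rankings, scope_members = NULL, weights = NULL,
                            top_n = NULL) {
  if (is.null(top_n)) {
    top_n <- attr(rankings, "top_n") %||% 10L
  }
  if (is.null(scope_members)) {
    scope_members <- unique(rankings$product)
  }
  if (length(scope_members) == 0L) {
    stop("empty scope", call. = FALSE)
  }
  df <- rankings[rankings$product %in% scope_members, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no rankings fall inside the scope {",
         paste(scope_members, collapse = ", "), "}", call. = FALSE)
  }
  blocks <- split(df, paste(df$study, df$product, sep = "\r"))
  scored <- dplyr::bind_rows(lapply(blocks, score_one_ranking, top_n = top_n))
  w <- rep(1, nrow(scored))
  if (!is.null(weights)) {
    missing <- setdiff(unique(scored$study), names(weights))
    if (length(missing) > 0L) {
      stop("no weight supplied for study(ies): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    w <- unname(weights[scored$study])
  }
  scored$wscore <- scored$score * w
  out <- scored |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(
      total_score = sum(.data$wscore),
      recurrence = dplyr::n_distinct(paste(.data$study, .data$product, sep = "\r")),
      best_position = min(.data$position),
      .groups = "drop"
    )
  tibble::as_tibble(out)
}

# score comparisons use an absolute tolerance; tie scores are halves so
# genuine ties are exact, but weighted sums may not be
SCORE_TOL <- 1e-9

#' Order Borda records into a consensus ranking
#'
#' Deterministic tie-break chain: total score (desc), then recurrence
#' (desc), then best position (asc), then display name (lexicographic).
#' Scores closer than 1e-9 are treated as equal. The `decided_by` column
#' records which key separated each record from its predecessor.
#'
#' @param records Tibble of Borda records from [aggregate_scope()].
#' @return A `consensus_ranking` tibble with `consensus_rank` and
#'   `decided_by` columns added.
#' @export
consensus <- function(records) {
  stopifnot(all(c("mirna", "total_score", "recurrence", "best_position")
                %in% names(records)))
  if (anyDuplicated(records$mirna)) {
    stop("duplicate miRNA in Borda records", call. = FALSE)
  }
  out <- dplyr::arrange(tibble::as_tibble(records),
                        dplyr::desc(.data$total_score),
                        dplyr::desc(.data$recurrence),
                        .data$best_position, .data$mirna)
  n <- nrow(out)
  decided <- character(n)
  decided[1] <- NA_character_
  if (n > 1L) {
    for (i in 2:n) {
      decided[i] <- if (out$total_score[i - 1] - out$total_score[i] > SCORE_TOL) {
        "score"
      } else if (out$recurrence[i - 1] != out$recurrence[i]) {
        "recurrence"
      } else if (out$best_position[i - 1] != out$best_position[i]) {
        "best_position"
      } else {
        "name"
      }
    }
  }
  out$consensus_rank <- seq_len(n)
  out$decided_by <- decided
  class(out) <- c("consensus_ranking", class(out))
  out
}

#' Top-k miRNAs of a consensus ranking
#'
#' Returns the first `k` records' miRNAs. When record `k` and the records
#' after it tie on every key except the name, the whole tied run is
#' reported and flagged, so the cut never silently depends on
#' lexicographic order.
#'
#' @param cons A `consensus_ranking`.
#' @param k Number of names requested (>= 1).
#' @return Tibble `consensus_rank`, `mirna`, `boundary_tie` (logical).
#' @export
top_k <- function(cons, k) {
  stopifnot(inherits(cons, "consensus_ranking"))
  if (k < 1) {
    stop("k must be >= 1", call. = FALSE)
  }
  n <- nrow(cons)
  keep <- min(k, n)
  last <- keep
  tied_on_name_only <- function(i, j) {
    abs(cons$total_score[i] - cons$total_score[j]) <= SCORE_TOL &&
      cons$recurrence[i] == cons$recurrence[j] &&
      cons$best_position[i] == cons$best_position[j]
  }
  while (last < n && tied_on_name_only(keep, last + 1L)) {
    last <- last + 1L
  }
  boundary <- logical(last)
  if (last > keep) {
    # flag the whole run that straddles the cut
    first_tied <- keep
    while (first_tied > 1L && tied_on_name_only(first_tied - 1L, keep)) {
      first_tied <- first_tied - 1L
    }
    boundary[first_tied:last] <- TRUE
  }
  tibble::tibble(
    consensus_rank = cons$consensus_rank[seq_len(last)],
    mirna = cons$mirna[seq_len(last)],
    boundary_tie = boundary
  )
}

#' Write a consensus ranking as TSV
#'
#' Columns: `mirna`, `total_score`, `recurrence`, `best_position`,
#' `consensus_rank`.
#'
#' @param cons A `consensus_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(cons, path) {
  readr::write_tsv(
    cons[, c("mirna", "total_score", "recurrence", "best_position",
             "consensus_rank")],
    path, progress = FALSE)
  invisible(path)
}
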