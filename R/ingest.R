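#' Read per-study top-N ranking tables
#'
#' One row per ranked miRNA. Required header columns: `study`, `product`,
#' `rank`, `mirna`, `tie` (the tie column may be empty). Rows are grouped by
#' (study, product), names canonicalized, and entries sorted by rank.
#' Several rows may share a rank only when they also share a non-empty tie
#' token; such a tie group spans the run of positions it occupies (see
#' [tie_scores()]).
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"csv"`; default guessed from the extension.
#' @param top_n Number of positions that carry non-zero Borda score
#'   (default 10).
#' @param prefixes Species prefixes passed to [canonicalize()].
#' @return A `study_rankings` tibble: `study`, `product`, `position`,
#'   `mirna` (canonical display), `tie_group` (`NA` when untied), with a
#'   `top_n` attribute.
#' @export
read_rankings <- function(path, dialect = NULL, top_n = 10,
                          prefixes = mirna_prefixes()) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "csv"))
  reader <- if (dialect == "csv") readr::read_csv else readr::read_tsv
  raw <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                progress = FALSE)
  required <- c("study", "product", "rank", "mirna", "tie")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0L) {
    stop("rankings file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  raw$.line <- seq_len(nrow(raw)) + 1L  # +1 for the header row
  raw$rank <- suppressWarnings(as.integer(raw$rank))
  if (anyNA(raw$rank)) {
    bad <- raw$.line[is.na(raw$rank)]
    stop("non-integer rank at line(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  raw$mirna <- canonical_names(raw$mirna, prefixes = prefixes)
  raw$tie <- ifelse(is.na(raw$tie) | !nzchar(trimws(raw$tie)),
                    NA_character_, trimws(raw$tie))

  errors <- character(0)
  for (key in split(raw, paste(raw$study, raw$product, sep = "\r"))) {
    dup <- key$mirna[duplicated(key$mirna)]
    for (d in unique(dup)) {
      lines <- key$.line[key$mirna == d]
      errors <- c(errors, sprintf(
        "duplicate miRNA '%s' within study '%s' / product '%s' (lines %s)",
        d, key$study[1], key$product[1], paste(lines, collapse = ", ")))
    }
    key <- key[order(key$rank, key$.line), ]
    same_pos <- duplicated(key$rank)
    if (any(same_pos)) {
      for (p in unique(key$rank[same_pos])) {
        grp <- key$tie[key$rank == p]
        if (anyNA(grp) || length(unique(grp)) != 1L) {
          errors <- c(errors, sprintf(
            "rows sharing rank %d in study '%s' / product '%s' must share a tie token (lines %s)",
            p, key$study[1], key$product[1],
            paste(key$.line[key$rank == p], collapse = ", ")))
        }
      }
    }
    pos <- sort(unique(key$rank))
    if (pos[1] < 1L) {
      errors <- c(errors, sprintf(
        "rank below 1 in study '%s' / product '%s'", key$study[1], key$product[1]))
    }
    if (length(pos) > 1L && any(diff(pos) > 1L)) {
      warning(sprintf(
        "rank gap in study '%s' / product '%s' (positions %s); positions kept as given",
        key$study[1], key$product[1], paste(pos, collapse = ",")),
        call. = FALSE)
    }
  }
  if (length(errors) > 0L) {
    stop(paste(errors, collapse = "\n"), call. = FALSE)
  }

  out <- tibble::tibble(
    study = raw$study,
    product = raw$product,
    position = raw$rank,
    mirna = raw$mirna,
    tie_group = raw$tie
  )
  out <- dplyr::arrange(out, .data$study, .data$product, .data$position,
                        .data$mirna)
  attr(out, "top_n") <- as.integer(top_n)
  class(out) <- c("study_rankings", class(out))
  out
}

#' Write ranking tables in the ingest dialect
#'
#' Inverse of [read_rankings()]; reading the written file back yields the
#' same `study_rankings` object.
#'
#' @param rankings A `study_rankings` tibble.
#' @param path Output file path (`.tsv` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_rankings <- function(rankings, path) {
  df <- tibble::tibble(
    study = rankings$study,
    product = rankings$product,
    rank = rankings$position,
    mirna = rankings$mirna,
    tie = ifelse(is.na(rankings$tie_group), "", rankings$tie_group)
  )
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(path)
}

#' Read the product metadata config
#'
#' YAML or JSON of the form
#' `products: {id: {group: dairy, state: raw, label: "Cow milk"}}`.
#' Groups and states are validated against closed vocabularies.
#'
#' @param path Config file path.
#' @param groups Allowed group tokens (default the five ASF groups); `NULL`
#'   accepts whatever groups the file declares (synthetic vocabularies).
#' @param states Allowed state tokens.
#' @return Tibble `product_id`, `group`, `state`, `label`.
#' @export
read_products <- function(path, groups = asf_groups(), states = asf_states()) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$products) || length(cfg$products) == 0L) {
    stop("config ", path, " has no 'products' block", call. = FALSE)
  }
  ids <- names(cfg$products)
  if (anyDuplicated(ids)) {
    stop("duplicate product ids in ", path, call. = FALSE)
  }
  rows <- purrr::imap(cfg$products, function(p, id) {
    if (is.null(p$group) || (!is.null(groups) && !(p$group %in% groups))) {
      stop(sprintf("product '%s' has unknown group '%s' (allowed: %s)",
                   id, p$group %||% "<missing>", paste(groups, collapse = ", ")),
           call. = FALSE)
    }
    if (is.null(p$state) || !(p$state %in% states)) {
      stop(sprintf("product '%s' has unknown state '%s' (allowed: %s)",
                   id, p$state %||% "<missing>", paste(states, collapse = ", ")),
           call. = FALSE)
    }
    tibble::tibble(product_id = id, group = p$group, state = p$state,
                   label = p$label %||% id)
  })
  dplyr::bind_rows(rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct a presence matrix
#'
#' Long-form membership of canonical miRNAs in (food group, processing
#' state) cells, with a free-text provenance label per cell.
#'
#' @param df Data frame with columns `mirna` (canonical display), `group`,
#'   `state` and optionally `source`.
#' @param groups,states Allowed vocabularies (any group set is accepted for
#'   synthetic runs; states must be raw/processed).
#' @return A `presence_matrix` tibble (distinct rows, arranged).
#' @export
presence_matrix <- function(df, groups = unique(df$group),
                            states = asf_states()) {
  stopifnot(all(c("mirna", "group", "state") %in% names(df)))
  if (!all(df$state %in% states)) {
    stop("unknown state token(s): ",
         paste(setdiff(unique(df$state), states), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$group %in% groups)) {
    stop("unknown group token(s): ",
         paste(setdiff(unique(df$group), groups), collapse = ", "),
         call. = FALSE)
  }
  if (!("source" %in% names(df))) {
    df$source <- NA_character_
  }
  out <- tibble::as_tibble(df[, c("mirna", "group", "state", "source")])
  out <- dplyr::distinct(dplyr::arrange(out, .data$mirna, .data$group,
                                        .data$state, .data$source))
  attr(out, "groups") <- groups
  class(out) <- c("presence_matrix", class(out))
  out
}

#' Load the packaged raw/processed presence fixtures
#'
#' Reads the packaged transcriptions of the conserved-homolog presence
#' tables (one TSV per state; `mirna` plus a `;`-separated `sources`
#' column), maps each atomic source label to its (group, state) cell via
#' the packaged source-group dictionary, and returns one presence matrix
#' covering both states.
#'
#' @return A `presence_matrix` with provenance labels.
#' @export
load_table_fixtures <- function() {
  ext <- function(f) system.file("extdata", f, package = "mirank", mustWork = TRUE)
  src_map <- readr::read_tsv(ext("source_groups.tsv"),
                             col_types = "ccc", progress = FALSE)
  read_one <- function(file, state) {
    tab <- readr::read_tsv(ext(file), col_types = "cc", progress = FALSE)
    long <- tidyr::separate_rows(tab, "sources", sep = ";")
    long$sources <- trimws(long$sources)
    long <- dplyr::left_join(long, src_map, by = c(sources = "source"))
    if (anyNA(long$group)) {
      stop("fixture source label(s) missing from source_groups.tsv: ",
           paste(unique(long$sources[is.na(long$group)]), collapse = "; "),
           call. = FALSE)
    }
    bad_state <- long$state != state
    if (any(bad_state)) {
      stop("fixture ", file, " references source(s) of the wrong state: ",
           paste(unique(long$sources[bad_state]), collapse = "; "),
           call. = FALSE)
    }
    tibble::tibble(
      mirna = canonical_names(long$mirna),
      group = long$group,
      state = long$state,
      source = long$sources
    )
  }
  df <- dplyr::bind_rows(
    read_one("table2_raw.tsv", "raw"),
    read_one("table3_processed.tsv", "processed")
  )
  presence_matrix(df, groups = asf_groups())
}

#' Conserved allow-list packaged with the fixtures
#'
#' @return Sorted character vector of the 48 conserved display names.
#' @export
load_conserved_fixture <- function() {
  read_conserved_list(system.file("extdata", "conserved_mirnas.txt",
                                  package = "mirank", mustWork = TRUE))
}
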