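# Small in-code fixtures shared across test files.

# Write a rankings table (data frame with study/product/rank/mirna/tie)
# to a temp TSV and return the path.
write_rankings_file <- function(df, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  if (!("tie" %in% names(df))) {
    df$tie <- ""
  }
  readr::write_tsv(df, path, progress = FALSE)
  path
}

# One study ranking A..J at positions 1..10.
ten_row_ranking <- function(study = "s1", product = "p1") {
  data.frame(
    study = study, product = product, rank = 1:10,
    mirna = sprintf("miR-%d-5p", 101:110), tie = ""
  )
}

# A presence matrix built from a compact spec:
# list of c(mirna, group, state) triples.
pm_from_triples <- function(triples, groups = NULL) {
  df <- do.call(rbind, lapply(triples, function(x) {
    data.frame(mirna = x[1], group = x[2], state = x[3])
  }))
  if (is.null(groups)) groups <- unique(df$group)
  presence_matrix(df, groups = groups)
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# draw n from M with K successes, P(overlap >= x).
hyper_tail_enum <- function(x, K, n, M) {
  draws <- utils::combn(M, n)
  overlap <- colSums(matrix(draws <= K, nrow = n))
  mean(overlap >= x)
}

# Independent BH step-up: p * m / rank, cumulative min from the largest
# rank, capped at 1, returned in input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
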