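test_that("positional Borda scores follow the descending top-N rule", {
  expect_equal(borda_score(1, 10), 10)
  expect_equal(borda_score(10, 10), 1)
  expect_equal(borda_score(11, 10), 0)
  expect_equal(borda_score(1:12, 10), c(10:1, 0, 0))
  expect_equal(borda_score(2, 3), 2)
  expect_error(borda_score(0, 10))
})

test_that("tie groups share the mean of their spanned scores", {
  expect_equal(tie_scores(c(10, 11), 10), 0.5)
  expect_equal(tie_scores(c(1, 2), 10), 9.5)
  expect_equal(tie_scores(5, 10), 6)
  expect_error(tie_scores(c(3, 5), 10), "contiguous")
})

test_that("a single full top-10 study yields scores 10..1 with mass 55", {
  r <- read_rankings(write_rankings_file(ten_row_ranking()))
  recs <- aggregate_scope(r)
  expect_equal(sum(recs$total_score), 55)
  ord <- recs[order(recs$best_position), ]
  expect_equal(ord$total_score, as.numeric(10:1))
  expect_true(all(recs$recurrence == 1))
})

test_that("Borda mass is conserved under the boundary tie policy", {
  df <- ten_row_ranking()
  df <- rbind(df, data.frame(study = "s1", product = "p1", rank = 10,
                             mirna = "miR-999-5p", tie = ""))
  df$tie[df$rank == 10] <- "A"
  r <- read_rankings(write_rankings_file(df))
  recs <- aggregate_scope(r)
  expect_equal(sum(recs$total_score), 55)
  expect_equal(recs$total_score[recs$mirna == "miR-999-5p"], 0.5)
  expect_equal(recs$total_score[recs$mirna == "miR-110-5p"], 0.5)
})

test_that("an interior tie spans the run of slots starting at its rank", {
  df <- data.frame(study = "s1", product = "p1",
                   rank = c(1, 2, 2, 4, 5),
                   mirna = sprintf("miR-%d", 1:5),
                   tie = c("", "B", "B", "", ""))
  r <- suppressWarnings(read_rankings(write_rankings_file(df)))
  recs <- aggregate_scope(r, top_n = 10)
  expect_equal(recs$total_score[recs$mirna == "miR-2"], 8.5)  # mean(9, 8)
  expect_equal(recs$total_score[recs$mirna == "miR-3"], 8.5)
  expect_equal(recs$total_score[recs$mirna == "miR-4"], 7)
})

test_that("aggregation sums weighted per-study scores with recurrence and best position", {
  df <- rbind(
    data.frame(study = "s1", product = "p1", rank = 1:10,
               mirna = c("miR-500-5p", sprintf("miR-6%02d-5p", 1:9)),
               tie = ""),
    data.frame(study = "s2", product = "p1", rank = 1:10,
               mirna = c(sprintf("miR-7%02d-5p", 1:3), "miR-500-5p",
                         sprintf("miR-7%02d-5p", 4:9)), tie = "")
  )
  r <- read_rankings(write_rankings_file(df))
  recs <- aggregate_scope(r)
  x <- recs[recs$mirna == "miR-500-5p", ]
  expect_equal(x$total_score, 17)  # 10 at position 1 plus 7 at position 4
  expect_equal(x$recurrence, 2)
  expect_equal(x$best_position, 1)

  # two identical studies double every score and preserve the order
  dup <- rbind(ten_row_ranking("s1"), ten_row_ranking("s2"))
  r1 <- aggregate_scope(read_rankings(write_rankings_file(ten_row_ranking())))
  r2 <- aggregate_scope(read_rankings(write_rankings_file(dup)))
  merged <- merge(r1, r2, by = "mirna")
  expect_equal(merged$total_score.y, 2 * merged$total_score.x)
})

test_that("aggregation is invariant to study and row order", {
  df <- rbind(ten_row_ranking("s1"), ten_row_ranking("s2", "p2"))
  df$mirna[15] <- "miR-501-3p"
  r <- read_rankings(write_rankings_file(df))
  shuffled <- r[rev(seq_len(nrow(r))), ]
  attr(shuffled, "top_n") <- attr(r, "top_n")
  class(shuffled) <- class(r)
  a <- aggregate_scope(r)
  b <- aggregate_scope(shuffled)
  expect_equal(dplyr::arrange(a, mirna), dplyr::arrange(b, mirna))
})

test_that("uniform study weights only rescale scores, never reorder", {
  df <- rbind(ten_row_ranking("s1"), ten_row_ranking("s2"))
  df$mirna[11:20] <- sprintf("miR-%d-3p", 201:210)
  r <- read_rankings(write_rankings_file(df))
  w <- c(s1 = 3, s2 = 3)
  plain <- consensus(aggregate_scope(r))
  scaled <- consensus(aggregate_scope(r, weights = w))
  expect_equal(scaled$mirna, plain$mirna)
  expect_equal(scaled$total_score, 3 * plain$total_score)
  expect_error(aggregate_scope(r, weights = c(s1 = 1)), "s2")
})

test_that("adding a first-place study never demotes a miRNA", {
  base <- rbind(ten_row_ranking("s1"), ten_row_ranking("s2"))
  r0 <- read_rankings(write_rankings_file(base))
  extra <- ten_row_ranking("s3")
  extra$mirna <- c("miR-105-5p", sprintf("miR-%d-5p", 301:309))
  r1 <- read_rankings(write_rankings_file(rbind(base, extra)))
  c0 <- consensus(aggregate_scope(r0))
  c1 <- consensus(aggregate_scope(r1))
  m <- "miR-105-5p"
  expect_gte(c1$total_score[c1$mirna == m], c0$total_score[c0$mirna == m])
  expect_lte(c1$consensus_rank[c1$mirna == m], c0$consensus_rank[c0$mirna == m])
})

test_that("empty scopes are fatal", {
  r <- read_rankings(write_rankings_file(ten_row_ranking()))
  expect_error(aggregate_scope(r, scope_members = character(0)), "empty scope")
  expect_error(aggregate_scope(r, scope_members = "absent"), "scope")
})

test_that("the consensus tie-break chain is score, recurrence, position, name", {
  recs <- tibble::tibble(
    mirna = c("miR-D", "miR-C", "miR-B", "miR-A", "miR-E"),
    total_score = c(12, 12, 12, 12, 20),
    recurrence = c(2, 1, 1, 1, 1),
    best_position = c(1, 1, 2, 2, 1)
  )
  cons <- consensus(recs)
  expect_equal(cons$mirna, c("miR-E", "miR-D", "miR-C", "miR-A", "miR-B"))
  expect_equal(cons$decided_by, c(NA, "score", "recurrence",
                                  "best_position", "name"))
  expect_error(consensus(rbind(recs, recs[1, ])), "duplicate")
})

test_that("top-k slices after ordering and flags boundary ties", {
  recs <- tibble::tibble(
    mirna = sprintf("miR-%02d", 1:6),
    total_score = c(30, 20, 10, 10, 10, 5),
    recurrence = 1, best_position = 1
  )
  cons <- consensus(recs)
  expect_error(top_k(cons, 0), ">= 1")
  expect_equal(nrow(top_k(cons, 100)), 6)

  cut <- top_k(cons, 4)  # records 3..5 tie on all keys but the name
  expect_equal(nrow(cut), 5)
  expect_equal(cut$boundary_tie, c(FALSE, FALSE, TRUE, TRUE, TRUE))

  clean <- top_k(cons, 2)
  expect_equal(clean$mirna, c("miR-01", "miR-02"))
  expect_false(any(clean$boundary_tie))
})
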