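test_that("within a food type, shared means at least two products' top lists", {
  sets <- list(
    beef_liver = c("miR-122-5p", "miR-148a-3p", "miR-192-5p"),
    rabbit_liver = c("miR-122-5p", "miR-99a-5p")
  )
  out <- shared_selective(sets)
  expect_equal(out$shared, "miR-122-5p")
  expect_equal(out$selective$beef_liver,
               sort(c("miR-148a-3p", "miR-192-5p")))
  expect_equal(out$selective$rabbit_liver, "miR-99a-5p")

  solo <- shared_selective(list(p1 = c("miR-1-3p", "miR-206")))
  expect_equal(solo$shared, character(0))
  expect_equal(solo$selective$p1, c("miR-1-3p", "miR-206"))

  three <- shared_selective(list(a = "miR-1-3p", b = "miR-1-3p",
                                 c = "miR-1-3p"))
  expect_equal(three$shared, "miR-1-3p")
  expect_error(shared_selective(list()), "at least one")
})

test_that("group exclusivity pools states and partitions the universe", {
  pm <- pm_from_triples(list(
    c("miR-1-3p", "lean_meat", "raw"),
    c("miR-1-3p", "dairy", "raw"),       # two groups -> shared
    c("miR-133b", "lean_meat", "processed"),
    c("miR-200c-3p", "dairy", "raw"),
    c("miR-200c-3p", "dairy", "processed")  # one group, both states
  ), groups = c("lean_meat", "dairy"))
  part <- group_exclusive(pm)
  expect_equal(part$exclusive$lean_meat, "miR-133b")
  expect_equal(part$exclusive$dairy, "miR-200c-3p")
  expect_equal(part$shared_multi_group, "miR-1-3p")

  # a true partition: disjoint exclusives whose union with shared covers all
  all_excl <- unlist(part$exclusive, use.names = FALSE)
  expect_equal(anyDuplicated(all_excl), 0L)
  expect_setequal(c(all_excl, part$shared_multi_group), unique(pm$mirna))

  single <- pm_from_triples(list(c("miR-1-3p", "dairy", "raw"),
                                 c("miR-206", "dairy", "raw")))
  expect_setequal(group_exclusive(single)$exclusive$dairy,
                  c("miR-1-3p", "miR-206"))
})

test_that("exclusivity is invariant under row permutation of the matrix", {
  pm <- load_table_fixtures()
  shuffled_df <- as.data.frame(pm)[rev(seq_len(nrow(pm))), ]
  pm2 <- presence_matrix(shuffled_df, groups = attr(pm, "groups"))
  expect_equal(group_exclusive(pm2)$exclusive, group_exclusive(pm)$exclusive)
})

test_that("removing a group's cells can only move a row toward exclusivity", {
  triples <- list(
    c("miR-1-3p", "lean_meat", "raw"),
    c("miR-1-3p", "dairy", "raw"),
    c("miR-206", "lean_meat", "raw")
  )
  pm_all <- pm_from_triples(triples, groups = c("lean_meat", "dairy"))
  pm_cut <- pm_from_triples(triples[-2], groups = c("lean_meat", "dairy"))
  before <- group_exclusive(pm_all)
  after <- group_exclusive(pm_cut)
  expect_true("miR-1-3p" %in% before$shared_multi_group)
  expect_true("miR-1-3p" %in% after$exclusive$lean_meat)
  # nothing already exclusive became shared
  expect_true(all(unlist(before$exclusive) %in% unlist(after$exclusive)))
})

test_that("persistence keeps exclusives with a processed-state cell", {
  pm <- pm_from_triples(list(
    c("miR-133b", "lean_meat", "raw"),
    c("miR-133b", "lean_meat", "processed"),
    c("miR-101-3p", "lean_meat", "raw"),
    c("miR-25-3p", "dairy", "raw")
  ), groups = c("lean_meat", "dairy"))
  part <- group_exclusive(pm)
  expect_equal(processing_persistence(part, pm), "miR-133b")

  raw_only <- pm_from_triples(list(c("miR-1-3p", "dairy", "raw")))
  expect_equal(processing_persistence(group_exclusive(raw_only), raw_only),
               character(0))
})

test_that("fixture partition reproduces the published exclusive sets", {
  pm <- load_table_fixtures()
  part <- group_exclusive(pm)
  expect_equal(lengths(part$exclusive[asf_groups()]),
               c(lean_meat = 3L, meat_fat = 3L, meat_offal = 3L,
                 dairy = 6L, seafood = 3L))
  expect_equal(part$exclusive$dairy,
               sort(c("miR-200a-3p", "miR-200c-3p", "miR-223-3p",
                      "miR-25-3p", "miR-29a-3p", "miR-29b-3p")))
  expect_equal(part$exclusive$lean_meat,
               sort(c("let-7d-5p", "miR-101-3p", "miR-133b")))
  expect_equal(part$exclusive$meat_fat,
               sort(c("let-7i-5p", "miR-30c-5p", "miR-23a-3p")))
  expect_equal(part$exclusive$meat_offal,
               sort(c("miR-145-5p", "miR-192-5p", "miR-24-3p")))
  # miR-30e-5p spans beef heart and pearl oyster, so it is shared
  expect_true("miR-30e-5p" %in% part$shared_multi_group)
  expect_equal(processing_persistence(part, pm),
               sort(c("miR-133b", "miR-23a-3p", "miR-192-5p",
                      "miR-200c-3p")))
})

test_that("universe counts distinguish raw, processed and union", {
  pm <- pm_from_triples(list(
    c("miR-1-3p", "dairy", "raw"),
    c("miR-206", "dairy", "raw"),
    c("miR-206", "dairy", "processed"),
    c("miR-133b", "dairy", "processed")
  ))
  counts <- universe_counts(pm)
  expect_equal(counts, list(n_raw = 2L, n_processed = 2L, n_union = 3L))
})

test_that("partitions serialize to JSON with per-group and shared blocks", {
  pm <- load_table_fixtures()
  part <- group_exclusive(pm)
  path <- withr::local_tempfile(fileext = ".json")
  write_partition(part, processing_persistence(part, pm), path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_setequal(names(back), c(asf_groups(), "shared", "persisted"))
  expect_equal(sort(back$dairy), part$exclusive$dairy)
  expect_equal(length(back$persisted), 4)
})
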