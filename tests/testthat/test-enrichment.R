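make_map <- function() {
  target_map(list(
    "miR-1-3p" = c("g1", "g2"),
    "miR-206" = c("g2", "g3"),
    "miR-133b" = c("g4")
  ))
}

test_that("common targets honour intersection, union and exclusivity modes", {
  map <- make_map()
  expect_equal(common_targets(c("miR-1-3p", "miR-206"), map, "all"), "g2")
  expect_equal(common_targets(c("miR-1-3p", "miR-206"), map, "any"),
               c("g1", "g2", "g3"))
  # exclusive: union minus every other miRNA's targets (g4 removes nothing)
  expect_equal(common_targets(c("miR-1-3p", "miR-206"), map, "exclusive"),
               c("g1", "g2", "g3"))
  expect_equal(common_targets("miR-1-3p", map, "exclusive"), "g1")

  ident <- target_map(list(a = c("g1", "g2"), b = c("g1", "g2")))
  expect_equal(common_targets(c("a", "b"), ident, "all"), c("g1", "g2"))
  disjoint <- target_map(list(a = "g1", b = "g2"))
  expect_equal(common_targets(c("a", "b"), disjoint, "all"), character(0))

  expect_error(common_targets(character(0), map), "empty")
  expect_error(common_targets("miR-999", map), "miR-999")
})

test_that("mode containments hold on random maps", {
  withr::with_seed(42, {
    for (i in 1:5) {
      genes <- sprintf("g%02d", 1:30)
      sets <- lapply(1:6, function(j) sample(genes, sample(3:12, 1)))
      names(sets) <- sprintf("m%d", 1:6)
      map <- target_map(sets)
      q <- sample(names(sets), 3)
      all_t <- common_targets(q, map, "all")
      any_t <- common_targets(q, map, "any")
      exc_t <- common_targets(q, map, "exclusive")
      expect_true(all(all_t %in% any_t))
      expect_true(all(exc_t %in% any_t))
    }
  })
})

test_that("coverage counts distinct targeting miRNAs per gene", {
  map <- target_map(list(a = "g", b = "g", c = character(0)))
  counts <- coverage_counts(map)
  expect_equal(unname(counts["g"]), 2L)
  expect_false("absent" %in% names(counts))

  full <- target_map(stats::setNames(rep(list("g"), 48),
                                     sprintf("m%02d", 1:48)))
  expect_equal(unname(coverage_counts(full)["g"]), 48L)
})

test_that("top-targeted selection thresholds, orders and truncates", {
  expect_equal(select_top_targeted(stats::setNames(integer(0), character(0))),
               character(0))
  counts <- stats::setNames(c(50, 45, 41, 39, 12), sprintf("g%d", 1:5))
  expect_equal(select_top_targeted(counts, min_mirnas = 40), c("g1", "g2", "g3"))
  expect_equal(select_top_targeted(counts, min_mirnas = 100), character(0))

  many <- stats::setNames(rep(41, 150), sprintf("g%03d", 1:150))
  expect_equal(length(select_top_targeted(many, min_mirnas = 40, cap = 100)),
               100)
  # ties broken by name ascending
  expect_equal(select_top_targeted(many, cap = 3), c("g001", "g002", "g003"))

  # fractional selector keeps the top share of covered genes
  expect_equal(select_top_targeted(counts, fraction = 0.4), c("g1", "g2"))
})

test_that("the hypergeometric tail matches exhaustive enumeration up to M = 12", {
  for (M in 2:12) {
    for (n in 1:M) {
      for (K in 1:M) {
        for (x in 0:min(K, n)) {
          expect_equal(hypergeom_p(x, K, n, M), hyper_tail_enum(x, K, n, M),
                       tolerance = 1e-12,
                       info = sprintf("x=%d K=%d n=%d M=%d", x, K, n, M))
        }
      }
    }
  }
})

test_that("worked tail case and boundary behaviour", {
  expect_equal(hypergeom_p(4, 4, 5, 10), 6 / 252, tolerance = 1e-12)
  expect_equal(hypergeom_p(0, 4, 5, 10), 1)
  expect_equal(hypergeom_p(5, 10, 5, 10), 1)  # all genes annotated
  expect_error(hypergeom_p(6, 4, 5, 10), "inconsistent")
  expect_error(hypergeom_p(1, 11, 5, 10), "inconsistent")

  # non-increasing in the overlap at fixed (K, n, M)
  p_seq <- vapply(0:5, hypergeom_p, numeric(1), K = 8, n = 5, M = 20)
  expect_true(all(diff(p_seq) <= 1e-15))
})

test_that("BH adjustment matches the independent step-up construction", {
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  withr::with_seed(7, {
    for (i in 1:5) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_stepup_oracle(p), tolerance = 1e-12)
      expect_true(all(q <= 1))
      # monotone: q never drops below the q of any smaller p
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), "pvalues")
})

test_that("GMT collections round-trip", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g2", "g4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_equal(read_gmt(path), sets)
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines("ONLY_NAME\tdesc", bad)
  expect_error(read_gmt(bad), "malformed")
})

test_that("ORA ranks an exactly-matching set first and uses the full BH family", {
  universe <- sprintf("g%03d", 1:100)
  sets <- list(
    HIT = universe[1:10],
    NEAR = universe[c(1:5, 50:54)],
    COLD = universe[60:69],
    WHOLE = universe
  )
  res <- run_ora(universe[1:10], sets, universe)
  expect_equal(res$set_name[1], "HIT")
  expect_equal(res$p[res$set_name == "WHOLE"], 1)
  expect_true(all(res$q >= res$p))
  expect_error(run_ora(character(0), sets, universe), "empty query")
  expect_error(run_ora("g001", sets, character(0)), "empty universe")
  expect_warning(run_ora(c("g001", "not_a_gene"), sets, universe),
                 "outside the universe")
})

test_that("target maps read from TSV deduplicate and canonicalize", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(data.frame(
    mirna = c("bta-miR-1-3p", "miR-1-3p", "miR-206"),
    gene = c("g1", "g1", "g2")), path, progress = FALSE)
  map <- read_target_map(path)
  expect_equal(map[["miR-1-3p"]], "g1")
  expect_setequal(attr(map, "universe"), c("g1", "g2"))
})
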