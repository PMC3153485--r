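test_that("gap trimming keeps columns strictly below the gap limit", {
  clean <- random_alignment(6, 30, seed = 1)
  out <- trim_gappy_columns(clean)
  expect_identical(unclass(out)[, ], unclass(clean)[, ])
  expect_identical(attr(out, "column_map"), 1:30)

  # 4 rows, column 2 has 2/4 = 0.5 gaps: removed (not < 0.5); a 1/4-gap
  # column stays
  aln <- alignment(c(r1 = "A-C", r2 = "A-C", r3 = "AEC", r4 = "AEC"))
  out2 <- trim_gappy_columns(aln)
  expect_identical(attr(out2, "column_map"), c(1L, 3L))
  aln3 <- alignment(c(r1 = "A-C", r2 = "AEC", r3 = "AEC", r4 = "AEC"))
  out3 <- trim_gappy_columns(aln3)
  expect_identical(attr(out3, "column_map"), 1:3)

  # hand-counted 4x6 case: gap fractions 0, .25, .5, .75, .25, .75
  hand <- alignment(c(r1 = "AA-AA-", r2 = "AAA-AA", r3 = "AA----",
                      r4 = "A-A-A-"))
  kept <- trim_gappy_columns(hand)
  expect_identical(attr(kept, "column_map"), c(1L, 2L, 5L))
  # mapping back reproduces the original column content
  expect_identical(unclass(hand)[, attr(kept, "column_map")],
                   unclass(kept)[, ])

  allgap <- alignment(c(r1 = "A--", r2 = "-A-", r3 = "--A"))
  expect_error(trim_gappy_columns(allgap), "gap")
})

test_that("fragment filtering applies the strict 100-residue boundary", {
  recs <- seq_records(c("short", "exact", "long"),
                      c(paste(rep("A", 99), collapse = ""),
                        paste(rep("A", 100), collapse = ""),
                        paste(rep("A", 150), collapse = "")))
  kept <- filter_fragments(recs)
  expect_identical(kept$id, c("exact", "long"))
  expect_equal(nrow(filter_fragments(recs[0, ])), 0)

  # every simulated fragment is removed, nothing else
  sim <- ref_simulation()
  all_records <- do.call(rbind, unname(sim$proteomes))
  kept_ref <- filter_fragments(all_records)
  removed <- setdiff(all_records$id, kept_ref$id)
  truth <- sim$truth$proteins
  expect_setequal(removed, truth$seq_id[truth$is_fragment])
})

test_that("identical aligned rows are collapsed to the first occurrence", {
  aln <- alignment(c(a = "ACDE", b = "ACDE", c = "ACDF"))
  out <- dedupe_identical(aln)
  expect_identical(rownames(out), c("a", "c"))

  distinct <- random_alignment(8, 20, seed = 3)
  expect_equal(nrow(dedupe_identical(distinct)), 8)

  set.seed(4)
  base <- random_alignment(6, 25, seed = 4)
  rows <- rshkit:::alignment_strings(base)
  dup <- alignment(stats::setNames(c(rows, rows[c(2, 5)]),
                                   c(names(rows), "x1", "x2")))
  expect_equal(nrow(dedupe_identical(dup)), 6)
})

test_that("consensus applies residue, class, gap and x rules in order", {
  k <- alignment(c(r1 = "K", r2 = "K", r3 = "K"))
  expect_equal(consensus(k, warn_duplicates = FALSE), "K")

  # 7 K + 3 R: neither residue reaches 0.7 but the basic class does
  rows <- c(rep("K", 7), rep("R", 3))
  basic <- alignment(stats::setNames(rows, paste0("r", 1:10)))
  expect_equal(consensus(basic, warn_duplicates = FALSE), "k")

  mixed <- alignment(stats::setNames(c("K", "D", "A", "F", "P", "C", "I",
                                       "N", "W", "E"), paste0("r", 1:10)))
  expect_equal(consensus(mixed, warn_duplicates = FALSE), "x")

  # gap call needs the residue and class rules to fail first
  gappy <- alignment(stats::setNames(c(rep("-A", 8), "KA", "DA"),
                                     paste0("r", 1:10)))
  expect_equal(consensus(gappy, warn_duplicates = FALSE), "-A")

  expect_error(consensus(k, threshold = 0.4), "threshold")
  expect_error(consensus(k, threshold = 1.2), "threshold")

  # tightening the threshold can only lose residue calls, never gain them
  set.seed(9)
  aln <- random_alignment(10, 60, seed = 9)
  c70 <- strsplit(consensus(aln, 0.70, warn_duplicates = FALSE), "")[[1]]
  c90 <- strsplit(consensus(aln, 0.90, warn_duplicates = FALSE), "")[[1]]
  calls <- c(LETTERS, setdiff(letters, "x"))   # residue or class symbols
  expect_false(any(c70 == "x" & c90 %in% calls))

  # idempotence: consensus of rows that all equal the consensus string
  cons <- consensus(aln, warn_duplicates = FALSE)
  cons_clean <- gsub("[a-z]", "A", gsub("x", "A", cons))
  again <- alignment(stats::setNames(rep(cons_clean, 3), paste0("c", 1:3)))
  expect_equal(consensus(again, warn_duplicates = FALSE), cons_clean)
})

test_that("column conservation categories match the comparative scheme", {
  cls <- function(sym, cons, focal = "RelA") {
    classify_column_conservation(sym, cons, focal)
  }
  sym <- c(Rel = "R", SpoT = "R", RelA = "R")
  expect_equal(cls(sym, c(Rel = TRUE, SpoT = TRUE, RelA = TRUE)),
               "UNIVERSAL")
  # the specificity-motif first position: focal E against conserved R
  sym2 <- c(Rel = "R", SpoT = "R", RelA = "E")
  expect_equal(cls(sym2, c(Rel = TRUE, SpoT = TRUE, RelA = TRUE)),
               "DISTINCTIVE_FOCAL")
  # focal conserved where the others have no consensus at all
  sym3 <- c(Rel = "x", SpoT = "x", RelA = "C")
  expect_equal(cls(sym3, c(Rel = FALSE, SpoT = FALSE, RelA = TRUE)),
               "DISTINCTIVE_FOCAL")
  # conserved in the non-focal pair, eroded in the focal subgroup
  sym4 <- c(Rel = "G", SpoT = "G", RelA = "x")
  expect_equal(cls(sym4, c(Rel = TRUE, SpoT = TRUE, RelA = FALSE)),
               "PAIR_NOT_FOCAL")
  sym5 <- c(Rel = "G", SpoT = "x", RelA = "G")
  expect_equal(cls(sym5, c(Rel = TRUE, SpoT = FALSE, RelA = TRUE)),
               "PAIR_NOT_SpoT")
  sym6 <- c(Rel = "A", SpoT = "x", RelA = "x")
  expect_equal(cls(sym6, c(Rel = TRUE, SpoT = FALSE, RelA = FALSE)),
               "UNCONSERVED")
  # class-compatible symbols (K vs basic class) count as agreement
  sym7 <- c(Rel = "K", SpoT = "k", RelA = "R")
  expect_equal(cls(sym7, c(Rel = TRUE, SpoT = TRUE, RelA = TRUE)),
               "UNIVERSAL")
  expect_error(cls(c(Rel = "R"), c(Rel = TRUE)), "at least 2")

  # permutation invariance over non-focal subgroups
  sym8 <- c(A = "G", B = "D", C = "G", RelA = "E")
  cons8 <- c(A = TRUE, B = FALSE, C = TRUE, RelA = TRUE)
  perm <- c("C", "B", "A", "RelA")
  expect_equal(cls(sym8, cons8), cls(sym8[perm], cons8[perm]))
})

test_that("group-specific sites separate in-group from out-group signal", {
  set.seed(12)
  base <- unclass(random_alignment(8, 20, seed = 12))
  base[1:4, 5] <- "C"                       # conserved only in the in-group
  base[1:4, 9] <- "G"; base[5:8, 9] <- "G"  # conserved everywhere
  aln <- alignment(base)
  found <- find_group_specific_sites(aln, paste0("s", 1:4), paste0("s", 5:8))
  expect_true(5 %in% found)
  expect_false(9 %in% found)

  expect_error(find_group_specific_sites(aln, paste0("s", 1:4),
                                         paste0("s", 4:8)), "overlap")
  expect_error(find_group_specific_sites(aln, "s1", paste0("s", 5:8)),
               "at least 2")
})

test_that("planted long-only conserved sites are recovered from the simulator", {
  sim <- ref_simulation()
  truth <- sim$truth$proteins
  aln <- sim$truth$domain_alns$SYNTH
  in_group <- truth$seq_id[truth$class %in% "long" & !truth$is_fragment]
  # contrast against one orthologous SAS cluster (a consensus comparison
  # over two distant paralog groups at once would dilute its conservation)
  out_group <- truth$seq_id[truth$subgroup %in% "SAS1" & !truth$is_fragment]
  planted <- sim$truth$conserved_in[[1]]$columns
  # specificity-motif columns are excluded from the evaluation: they are
  # fixed in the long subgroups but evolve at their base rate in SAS, so
  # whether they show up as long-only is left to chance, not planted
  motif <- vapply(sim$truth$fixed_substitutions[1:4], `[[`, numeric(1),
                  "column")
  found <- setdiff(find_group_specific_sites(aln, in_group, out_group),
                   motif)
  recall <- mean(planted %in% found)
  precision <- mean(found %in% planted)
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.8)
})
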