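test_that("Fitch counts match trivial cases and are root-invariant", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- alignment(c(a = "AAK", b = "AAR", c = "AKK", d = "A-K"))
  fc <- fitch_counts(tr, aln)
  expect_equal(fc$counts[[1]], 0)                  # invariant column
  expect_equal(fc$counts[[2]], 1)                  # one cherry differs
  expect_equal(fc$counts[[3]], 1)                  # gap treated as missing
  expect_equal(fc$tree_length, 6)

  rerooted <- ape::root(ape::unroot(tr), outgroup = "c",
                        resolve.root = TRUE)
  expect_equal(fitch_counts(rerooted, aln)$counts, fc$counts)

  expect_error(fitch_counts(tr, aln, clade = c("a", "b")), "at least 3")
})

test_that("Fitch counts equal brute-force minimal labelings on 6-leaf trees", {
  for (s in 1:12) {
    tr <- random_additive_tree(6, seed = 1500 + s)
    tr <- ape::root(tr, outgroup = tr$tip.label[[1]], resolve.root = TRUE)
    set.seed(1600 + s)
    mat <- matrix(sample(c("A", "C", "D", "E", "-"), 6 * 15, replace = TRUE,
                         prob = c(0.3, 0.3, 0.2, 0.1, 0.1)), 6, 15)
    # keep at least one residue per row
    mat[, 1] <- "A"
    rownames(mat) <- tr$tip.label
    aln <- alignment(mat)
    fc <- fitch_counts(tr, aln)
    for (j in seq_len(ncol(mat))) {
      states <- ifelse(mat[, j] == "-", NA, mat[, j])
      expect_equal(fc$counts[[j]], brute_fitch_column(tr, states),
                   info = sprintf("seed %d column %d", s, j))
    }
  }
})

test_that("type I divergence recovers the null and flags by the PP cutoff", {
  pair0 <- simulate_rate_shift_pair(seed = 1, fraction = 0, n_leaves = 12,
                                    n_columns = 120)
  ca <- fitch_counts(pair0$tree_a, pair0$aln_a)
  dv_null <- type1_divergence(ca, ca)
  expect_lte(dv_null$theta, 0.1)

  pair <- simulate_rate_shift_pair(seed = 2)
  a <- fitch_counts(pair$tree_a, pair$aln_a)
  b <- fitch_counts(pair$tree_b, pair$aln_b)
  dv <- type1_divergence(a, b)
  expect_true(dv$theta >= 0 && dv$theta <= 1)
  expect_identical(dv$flagged, which(dv$pp >= 0.90))

  swapped <- type1_divergence(b, a)
  expect_equal(swapped$theta, dv$theta, tolerance = 1e-6)
  expect_equal(swapped$pp, dv$pp, tolerance = 1e-6)

  expect_error(type1_divergence(a, list(counts = 1:3, tree_length = 1)),
               "columns")
})

test_that("stronger rate shifts never weaken the divergence posterior", {
  mean_pp <- vapply(c(2, 5, 10), function(mult) {
    pair <- simulate_rate_shift_pair(seed = 6, multiplier = mult)
    a <- fitch_counts(pair$tree_a, pair$aln_a)
    b <- fitch_counts(pair$tree_b, pair$aln_b)
    mean(type1_divergence(a, b)$pp[pair$shifted])
  }, numeric(1))
  expect_true(all(diff(mean_pp) > -1e-9))
})

test_that("type II sites require fixed, radical, differing residues", {
  mk <- function(res, n = 6) {
    alignment(stats::setNames(rep(res, n), paste0(substr(res, 1, 1), 1:n)))
  }
  a <- alignment(stats::setNames(rep("KAG", 6), paste0("a", 1:6)))
  b <- alignment(stats::setNames(rep("DAG", 6), paste0("b", 1:6)))
  expect_equal(type2_sites(a, b), 1)               # K vs D: basic vs acidic
  expect_equal(type2_sites(b, a), 1)               # symmetric
  expect_equal(length(type2_sites(a, a)), 0)       # identical clades

  b2 <- alignment(stats::setNames(rep("RAG", 6), paste0("b", 1:6)))
  expect_equal(length(type2_sites(a, b2)), 0)      # K vs R: same class

  # one dissenting row in ten breaks fixation at the 0.95 threshold
  rows <- c(rep("KAG", 9), "DAG")
  a3 <- alignment(stats::setNames(rows, paste0("a", 1:10)))
  expect_equal(length(type2_sites(a3, b)), 0)
})

test_that("the planted specificity-motif substitution is detected as type II", {
  sim <- ref_simulation()
  truth <- sim$truth$proteins
  aln <- sim$truth$domain_alns$SYNTH
  relA <- truth$seq_id[truth$subgroup %in% "LongA" & !truth$is_fragment]
  rel <- truth$seq_id[truth$subgroup %in% "LongB" & !truth$is_fragment]
  sites <- type2_sites(aln[relA, , drop = FALSE], aln[rel, , drop = FALSE])
  fixed <- sim$truth$fixed_substitutions
  motif1 <- fixed[[1]]$column                      # E vs R first position
  expect_true(motif1 %in% sites)
})

test_that("domain divergence ratios isolate the degraded domain", {
  # equal rates: ratios near 1
  ratios <- vapply(1:10, function(s) {
    tr <- rshkit:::scale_tree_depth(simulate_tree(8, seed = 1700 + s), 0.3)
    aln <- evolve_alignment(sample(AA20, 120, replace = TRUE), tr,
                            rep(1, 120), seed = 1800 + s)
    r <- domain_divergence_ratio(aln, rownames(aln),
                                 list(d1 = 1:60, d2 = 61:120))
    max(abs(r$ratio - 1))
  }, numeric(1))
  expect_lt(mean(ratios), 0.3)

  # the reference degraded-HD clade: HD diverges disproportionately
  sim <- ref_simulation()
  truth <- sim$truth$proteins
  relA <- truth$seq_id[truth$subgroup %in% "LongA" & !truth$is_fragment]
  doms <- sim$truth$domain_alns
  combined <- alignment(do.call(cbind, lapply(doms, function(a) {
    unclass(a)[relA, , drop = FALSE]
  })))
  widths <- vapply(doms, ncol, integer(1))
  offs <- cumsum(c(0, widths))
  cols <- lapply(seq_along(doms), function(i) (offs[[i]] + 1):offs[[i + 1]])
  names(cols) <- names(doms)
  rd <- domain_divergence_ratio(combined, relA, cols)
  expect_true(rd$degraded_like[rd$domain == "HD"])
  expect_gt(rd$ratio[rd$domain == "HD"], 2)
  expect_false(any(rd$degraded_like[rd$domain != "HD"]))

  # degenerate: identical sequences give ratio 1 by convention
  ident <- alignment(stats::setNames(rep("AAAACCCC", 4), paste0("i", 1:4)))
  rident <- domain_divergence_ratio(ident, paste0("i", 1:4),
                                    list(d1 = 1:4, d2 = 5:8))
  expect_equal(rident$ratio, c(1, 1))

  expect_error(domain_divergence_ratio(ident, paste0("i", 1:4),
                                       list(d1 = 1:4, d2 = integer(0))),
               "empty")
})

test_that("specificity motifs are read from the four motif columns", {
  expect_equal(specificity_motif("EFDD", 1:4), "GDP_type")
  expect_equal(specificity_motif("RFKD", 1:4), "GTP_type")
  expect_equal(specificity_motif("AAAA", 1:4), "unknown")
  expect_equal(specificity_motif("XXEFDDXX", 3:6), "GDP_type")
  expect_error(specificity_motif("EFDD", 2:5), "outside")

  # the simulated RelA analogue carries the GDP-type acidic motif,
  # the Rel/SpoT analogues the GTP-type basic motif
  sim <- ref_simulation()
  truth <- sim$truth$proteins
  aln <- sim$truth$domain_alns$SYNTH
  cols <- vapply(sim$truth$fixed_substitutions[1:4], `[[`, numeric(1),
                 "column")
  relA1 <- truth$seq_id[truth$subgroup %in% "LongA" &
                          !truth$is_fragment][[1]]
  rel1 <- truth$seq_id[truth$subgroup %in% "LongB" &
                         !truth$is_fragment][[1]]
  expect_equal(specificity_motif(unclass(aln)[relA1, ], cols), "GDP_type")
  expect_equal(specificity_motif(unclass(aln)[rel1, ], cols), "GTP_type")
})
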