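test_that("Poisson-corrected distances match closed forms and hand counts", {
  same <- alignment(c(a = "ACDEF", b = "ACDEF"))
  expect_equal(unname(poisson_distance(same)["a", "b"]), 0)

  half <- alignment(c(a = "AAAA", b = "AACC"))     # p = 0.5
  expect_equal(unname(poisson_distance(half)["a", "b"]), log(2),
               tolerance = 1e-12)

  # 3-row toy, hand-counted over shared non-gap columns:
  # a-b: 6 shared, 2 mismatches; a-c: 5 shared, 2; b-c: 5 shared, 3
  toy <- alignment(c(a = "ACDEFG", b = "ACDKFG", c = "AC-EYH"))
  D <- poisson_distance(toy)
  expect_equal(unname(D["a", "b"]), -log(1 - 1 / 6), tolerance = 1e-12)
  expect_equal(unname(D["a", "c"]), -log(1 - 2 / 5), tolerance = 1e-12)
  expect_equal(unname(D["b", "c"]), -log(1 - 3 / 5), tolerance = 1e-12)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))

  sat <- alignment(c(a = paste(rep("A", 40), collapse = ""),
                     b = paste(rep("C", 40), collapse = "")))
  expect_warning(Ds <- poisson_distance(sat), "capped")
  expect_equal(unname(Ds["a", "b"]), 10)

  nosh <- alignment(c(a = "AC--", b = "--DE", c = "ACDE"))
  expect_error(poisson_distance(nosh), "'a' and 'b'")
})

test_that("neighbor joining is exact on additive matrices", {
  for (s in 1:50) {
    n <- 4 + (s %% 5)
    tr <- random_additive_tree(n, seed = 900 + s)
    D <- ape::cophenetic.phylo(tr)
    nj <- nj_tree(D)
    expect_equal(phangorn::RF.dist(nj, tr), 0)
    expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
  tri <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
                dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(nj_tree(tri)$tip.label), 3)
  expect_error(nj_tree(tri[1:2, 1:2]), "at least 3")
})

test_that("the true tree metric is recovered from noiseless distances", {
  sim <- ref_simulation()
  tr <- sim$truth$tree
  set.seed(61)
  keep <- sample(tr$tip.label, 40)
  sub <- ape::keep.tip(tr, keep)
  D <- ape::cophenetic.phylo(sub)
  nj <- nj_tree(D)
  # the true tree has a root polytomy, so compare the additive metric
  # (equal path lengths imply the same resolved topology)
  expect_equal(ape::cophenetic.phylo(nj)[rownames(D), colnames(D)], D,
               tolerance = 1e-6)
})

test_that("bootstrap supports reflect the signal in the columns", {
  # every column splits {A,B} from {C,D}
  set.seed(33)
  n_col <- 40
  ab <- sample(AA20, n_col, replace = TRUE)
  cd <- vapply(ab, function(x) sample(setdiff(AA20, x), 1), character(1))
  flip <- function(x, p) ifelse(runif(n_col) < p,
                                sample(AA20, n_col, replace = TRUE), x)
  aln <- alignment(rbind(A = ab, B = flip(ab, 0.1), C = cd,
                         D = flip(cd, 0.1)))
  tr <- bootstrap_supports(aln, n_replicates = 100, seed = 2)
  mono <- is_monophyletic(tr, c("A", "B"))
  expect_true(mono$monophyletic)
  expect_equal(mono$support, 100)

  tr2 <- bootstrap_supports(aln, n_replicates = 100, seed = 2)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))

  sup <- suppressWarnings(as.numeric(tr$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("bootstrap supports are invariant to leaf order", {
  aln <- random_alignment(6, 80, seed = 44)
  perm <- alignment(unclass(aln)[sample(6), , drop = FALSE])
  t1 <- bootstrap_supports(aln, n_replicates = 50, seed = 5)
  t2 <- bootstrap_supports(perm, n_replicates = 50, seed = 5)
  key <- function(tr) {
    k <- rshkit:::tree_bipart_keys(tr)
    sup <- tr$node.label
    stats::setNames(sup[!is.na(k)], k[!is.na(k)])
  }
  k1 <- key(t1); k2 <- key(t2)
  shared <- intersect(names(k1), names(k2))
  expect_gt(length(shared), 0)
  expect_identical(k1[shared], k2[shared])
})

test_that("midpoint rooting sits on the longest path and preserves distances", {
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  expect_equal(midpoint_root(cherry)$edge.length, c(1, 1))

  cat <- ape::read.tree(text = "(((a:0.1,b:0.1):0.1,c:0.1):0.1,d:5);")
  rooted <- midpoint_root(cat)
  root_children <- rooted$edge[rooted$edge[, 1] == length(rooted$tip.label) + 1, 2]
  d_leaf <- which(rooted$tip.label == "d")
  expect_true(d_leaf %in% root_children)   # root placed on d's long branch

  tr <- random_additive_tree(8, seed = 21)
  rooted2 <- midpoint_root(tr)
  expect_equal(ape::cophenetic.phylo(rooted2)[tr$tip.label, tr$tip.label],
               ape::cophenetic.phylo(tr), tolerance = 1e-8)
})

test_that("monophyly testing matches edge bipartitions", {
  tr <- ape::read.tree(text = "((a:1,b:1)90:1,(c:1,d:1)80:1);")
  expect_true(is_monophyletic(tr, c("a", "b"))$monophyletic)
  expect_equal(is_monophyletic(tr, c("a", "b"))$support, 90)
  expect_false(is_monophyletic(tr, c("a", "c"))$monophyletic)
  expect_error(is_monophyletic(tr, c("a", "z")), "unknown")

  # constructive: the leaf set under any internal edge is monophyletic
  for (s in 1:10) {
    rt <- random_additive_tree(8, seed = 1200 + s)
    parts <- ape::prop.part(rt)
    sizes <- lengths(parts)
    ok <- which(sizes >= 2 & sizes <= 6)
    nd <- ok[[1 + (s %% length(ok))]]
    clade <- rt$tip.label[parts[[nd]]]
    expect_true(is_monophyletic(rt, clade)$monophyletic)
  }
})

test_that("subgroup extraction emits supported compact clades only", {
  two <- ape::read.tree(text = paste0(
    "((a1:0.1,a2:0.1,a3:0.1,a4:0.1,a5:0.1)100:1.5,",
    "(b1:0.1,b2:0.1,b3:0.1,b4:0.1,b5:0.1)100:1.5)root;"))
  out <- extract_subgroups(two)
  expect_equal(length(out$subgroups), 2)
  expect_equal(length(out$unassigned), 0)
  expect_setequal(out$subgroups$SG1, paste0("a", 1:5))

  weak <- ape::read.tree(text = paste0(
    "((a1:0.1,a2:0.1,a3:0.1,a4:0.1,a5:0.1)30:1.5,",
    "(b1:0.1,b2:0.1,b3:0.1,b4:0.1,b5:0.1)40:1.5)root;"))
  out2 <- extract_subgroups(weak)
  expect_equal(length(out2$subgroups), 0)
  expect_equal(length(out2$unassigned), 10)

  small <- ape::read.tree(text = paste0(
    "((a1:0.1,a2:0.1,a3:0.1)100:1.5,",
    "(b1:0.1,b2:0.1,b3:0.1,b4:0.1,b5:0.1)100:1.5)root;"))
  out3 <- extract_subgroups(small)
  expect_false(any(vapply(out3$subgroups, function(g) {
    any(startsWith(g, "a"))
  }, logical(1))))                                  # size-3 clade unassigned
  expect_true(all(paste0("a", 1:3) %in% out3$unassigned))

  # output is a partition of the leaves
  all_leaves <- c(unlist(out3$subgroups), out3$unassigned)
  expect_setequal(all_leaves, small$tip.label)
  expect_equal(anyDuplicated(all_leaves), 0)
})
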