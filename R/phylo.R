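#' Poisson-corrected distance matrix from a protein alignment
#'
#' For each pair of rows, `p` is the mismatch fraction over mutually non-gap
#' (and non-`X`) columns and the distance is `d = -ln(1 - p)`, correcting
#' observed differences for multiple hits. Nearly saturated pairs
#' (`p >= 0.95`) are capped at `d = 10` with a warning; a pair sharing no
#' columns is an error.
#'
#' @param aln Alignment matrix with at least 2 rows.
#' @param saturation_p Mismatch fraction at which the correction is capped.
#' @param d_max Capped distance.
#' @return Symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
poisson_distance <- function(aln, saturation_p = 0.95, d_max = 10) {
  n <- nrow(aln)
  if (n < 2) stop("need at least 2 sequences", call. = FALSE)
  ids <- rownames(aln)
  ok <- aln != "-" & aln != "X"
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- ok[i, ] & ok[j, ]
      ns <- sum(shared)
      if (ns == 0) {
        stop(sprintf("no shared columns between '%s' and '%s'",
                     ids[[i]], ids[[j]]), call. = FALSE)
      }
      p <- sum(aln[i, shared] != aln[j, shared]) / ns
      if (p >= saturation_p) {
        d <- d_max; capped <- TRUE
      } else {
        d <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  if (capped) {
    warning(sprintf("saturated pair(s) capped at d = %g", d_max),
            call. = FALSE)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`); negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to 0.
#'
#' @param D Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An unrooted binary `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (nrow(D) < 3) stop("neighbor joining needs at least 3 taxa",
                        call. = FALSE)
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

# canonical key for the bipartition induced by a clade leaf set: the side
# not containing the alphabetically first taxon, sorted and pasted
bipart_key <- function(clade, all_taxa) {
  anchor <- min(all_taxa)
  side <- if (anchor %in% clade) setdiff(all_taxa, clade) else clade
  paste(sort(side), collapse = "\r")
}

# keys for every internal node of a tree (index = node number - Ntip);
# trivial bipartitions get NA
tree_bipart_keys <- function(tree) {
  nt <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  keys <- rep(NA_character_, tree$Nnode)
  for (nd in seq_len(tree$Nnode)) {
    clade <- tree$tip.label[parts[[nd]]]
    if (length(clade) < 2 || length(clade) > nt - 2) next  # trivial
    keys[[nd]] <- bipart_key(clade, tree$tip.label)
  }
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the full-data NJ tree from Poisson-corrected distances, midpoint
#' roots it, and attaches to each internal edge the percentage of
#' column-resampled replicates whose NJ tree contains the same bipartition.
#' Deterministic for a given seed.
#'
#' @param aln Alignment matrix (>= 4 rows).
#' @param n_replicates Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Rooted `phylo` tree whose `node.label` holds integer supports
#'   (0-100; `NA` on the root and on trivial bipartitions).
#' @export
bootstrap_supports <- function(aln, n_replicates = 100, seed = 1) {
  if (nrow(aln) < 4) stop("bootstrap needs at least 4 sequences",
                          call. = FALSE)
  # canonical row order: supports are then invariant to the input's
  # leaf order (NJ tie-breaking depends on matrix order)
  aln <- alignment(unclass(aln)[order(rownames(aln), method = "radix"), ,
                                drop = FALSE])
  main <- midpoint_root(nj_tree(suppressWarnings(poisson_distance(aln))))
  keys <- tree_bipart_keys(main)
  counts <- stats::setNames(rep(0L, sum(!is.na(keys))),
                            keys[!is.na(keys)])
  with_local_seed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_aln <- alignment(unclass(aln)[, cols, drop = FALSE])
      D <- tryCatch(suppressWarnings(poisson_distance(rep_aln)),
                    error = function(e) NULL)
      if (is.null(D)) next
      rep_keys <- tree_bipart_keys(nj_tree(D))
      hit <- intersect(names(counts), rep_keys)
      counts[hit] <- counts[hit] + 1L
    }
  })
  support <- rep(NA_integer_, main$Nnode)
  has <- !is.na(keys)
  support[has] <- as.integer(round(100 * counts[keys[has]] / n_replicates))
  main$node.label <- ifelse(is.na(support), "", as.character(support))
  main
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (via `phangorn::midpoint`). Pairwise leaf path lengths are preserved.
#'
#' @param tree A `phylo` tree with >= 2 leaves.
#' @return Rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (length(tree$tip.label) < 2) stop("need at least 2 leaves",
                                       call. = FALSE)
  if (length(tree$tip.label) == 2) return(tree)
  phangorn::midpoint(tree)
}

#' Test a label set for monophyly
#'
#' True when some edge bipartition of the (unrooted view of the) tree
#' splits exactly the query labels from the rest; the bootstrap support of
#' that edge is returned when node labels carry supports (`-1` when
#' absent).
#'
#' @param tree A `phylo` tree.
#' @param labels Character vector of leaf labels.
#' @return List with `monophyletic` (logical) and `support` (integer).
#' @export
is_monophyletic <- function(tree, labels) {
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) {
    stop(sprintf("unknown leaf label '%s'", unknown[[1]]), call. = FALSE)
  }
  nt <- length(tree$tip.label)
  if (length(labels) %in% c(0, nt)) {
    return(list(monophyletic = TRUE, support = -1L))
  }
  if (length(labels) == 1 || length(labels) == nt - 1) {
    return(list(monophyletic = TRUE, support = -1L))
  }
  want <- bipart_key(labels, tree$tip.label)
  keys <- tree_bipart_keys(tree)
  nd <- which(!is.na(keys) & keys == want)
  if (!length(nd)) return(list(monophyletic = FALSE, support = -1L))
  sup <- -1L
  if (!is.null(tree$node.label)) {
    lab <- tree$node.label[[nd[[1]]]]
    if (!is.na(lab) && nzchar(lab)) sup <- as.integer(round(as.numeric(lab)))
  }
  list(monophyletic = TRUE, support = sup)
}

#' Extract well-supported, compact subgroups from a tree
#'
#' Greedy top-down traversal from the root: a clade is emitted as a
#' subgroup when its support is at least `min_support`, it has at least
#' `min_size` leaves, and its mean intra-clade leaf path distance is at
#' most `compactness * (mean tree-wide leaf path distance)`; the traversal
#' does not descend into emitted clades, so subgroups are disjoint and
#' maximal. Remaining leaves form the unassigned pool. Subgroups are named
#' `SG1`, `SG2`, ... by decreasing size (ties by first leaf label).
#'
#' @param tree Rooted `phylo` tree with supports in `node.label` (as
#'   produced by [bootstrap_supports()]).
#' After the traversal, emitted groups that are not genuinely separate
#' subfamilies are merged. Subgroups in this superfamily are orthologous
#' subfamilies with single representatives per genome, so when a leaf-to-
#' genome mapping is supplied the primary merge signal is genome
#' co-occurrence: two groups drawn from (nearly) disjoint genome sets are
#' sub-clades of one orthologous cluster, while true paralogous subgroups
#' co-occur in the same genomes. A stem-versus-crown guard (the stem
#' separating the pair, cross-group mean distance minus average
#' within-group mean, must not exceed `stem_cap` crown lengths) prevents
#' uniting genuinely distant groups that merely have complementary genome
#' coverage. Without a genome mapping only the stem rule is used, at the
#' conservative `merge_ratio`.
#'
#' @param min_support Minimum bootstrap percentage.
#' @param min_size Minimum number of leaves.
#' @param compactness Multiplier on the tree-wide mean leaf distance.
#' @param merge_ratio Stem/crown merge threshold when no genome mapping
#'   is available.
#' @param genomes Optional named character vector mapping leaf labels to
#'   genome ids.
#' @param max_genome_overlap Maximum tolerated fraction of shared genomes
#'   (relative to the smaller group) for a genome-based merge.
#' @param stem_cap Stem/crown guard for genome-based merges.
#' @return List with `subgroups` (named list of leaf-label vectors) and
#'   `unassigned` (character vector).
#' @export
extract_subgroups <- function(tree, min_support = 60, min_size = 4,
                              compactness = 0.5, merge_ratio = 1.5,
                              genomes = NULL, max_genome_overlap = 0.1,
                              stem_cap = 2.5) {
  if (is.null(tree$node.label)) {
    stop("tree carries no support values", call. = FALSE)
  }
  nt <- length(tree$tip.label)
  coph <- ape::cophenetic.phylo(tree)
  global_mean <- mean(coph[upper.tri(coph)])
  node_support <- suppressWarnings(as.numeric(tree$node.label))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  clades <- ape::prop.part(tree)

  emitted <- list()
  unassigned <- character(0)
  visit <- function(node) {
    if (node <= nt) {
      unassigned <<- c(unassigned, tree$tip.label[[node]])
      return(invisible(NULL))
    }
    leaves <- tree$tip.label[clades[[node - nt]]]
    sup <- node_support[[node - nt]]
    ok_support <- !is.na(sup) && sup >= min_support
    ok_size <- length(leaves) >= min_size
    ok_compact <- FALSE
    if (ok_support && ok_size) {
      sub <- coph[leaves, leaves]
      ok_compact <- mean(sub[upper.tri(sub)]) <= compactness * global_mean
    }
    if (ok_support && ok_size && ok_compact) {
      emitted[[length(emitted) + 1]] <<- leaves
    } else {
      for (ch in children[[as.character(node)]]) visit(ch)
    }
    invisible(NULL)
  }
  root <- nt + 1L
  for (ch in children[[as.character(root)]]) visit(ch)

  # merge emitted groups that are not genuinely separated
  intra_mean <- function(lv) {
    if (length(lv) < 2) return(0)
    m <- coph[lv, lv]
    mean(m[upper.tri(m)])
  }
  should_merge <- function(gi, gj) {
    wi <- intra_mean(gi); wj <- intra_mean(gj)
    stem_ratio <- (mean(coph[gi, gj]) - (wi + wj) / 2) /
      max(mean(c(wi, wj)), 1e-12)
    if (is.null(genomes)) return(stem_ratio <= merge_ratio)
    shared <- length(intersect(unique(genomes[gi]), unique(genomes[gj])))
    overlap <- shared / min(length(unique(genomes[gi])),
                            length(unique(genomes[gj])))
    overlap <= max_genome_overlap && stem_ratio <= stem_cap
  }
  repeat {
    if (length(emitted) < 2) break
    merged <- FALSE
    for (i in seq_len(length(emitted) - 1)) {
      for (j in (i + 1):length(emitted)) {
        if (should_merge(emitted[[i]], emitted[[j]])) {
          emitted[[i]] <- c(emitted[[i]], emitted[[j]])
          emitted[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }

  ord <- order(-lengths(emitted),
               vapply(emitted, function(x) sort(x)[[1]], character(1)),
               method = "radix")
  emitted <- emitted[ord]
  names(emitted) <- if (length(emitted)) paste0("SG", seq_along(emitted))
                    else character(0)
  list(subgroups = emitted, unassigned = sort(unassigned, method = "radix"))
}
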