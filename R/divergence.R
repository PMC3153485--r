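#' Per-site Fitch parsimony substitution counts for a clade
#'
#' Restricts the tree to the clade's leaves and, for every alignment
#' column, computes the Fitch minimum number of state changes on the
#' subtree. Gaps and `X` are treated as missing data (the leaf's state set
#' is the full alphabet, so it never forces a change). The count is
#' invariant to the arbitrary internal rooting used.
#'
#' @param tree `phylo` tree containing the clade leaves.
#' @param aln Alignment matrix whose rows include the clade leaves.
#' @param clade Character vector of leaf ids (>= 3).
#' @return List with `counts` (integer per column), `tree_length` (sum of
#'   clade-subtree branch lengths) and `clade` (the leaf ids used).
#' @export
fitch_counts <- function(tree, aln, clade = NULL) {
  if (is.null(clade)) clade <- intersect(tree$tip.label, rownames(aln))
  if (length(clade) < 3) stop("clade must have at least 3 leaves",
                              call. = FALSE)
  missing <- setdiff(clade, tree$tip.label)
  if (length(missing)) stop(sprintf("leaf '%s' not in tree", missing[[1]]),
                            call. = FALSE)
  missing <- setdiff(clade, rownames(aln))
  if (length(missing)) stop(sprintf("leaf '%s' not in alignment",
                                    missing[[1]]), call. = FALSE)
  sub <- ape::keep.tip(tree, clade)
  nt <- length(sub$tip.label)
  ord <- ape::reorder.phylo(sub, "postorder")
  sub_aln <- aln[sub$tip.label, , drop = FALSE]
  counts <- integer(ncol(aln))
  full <- AA
  node_children <- split(ord$edge[, 2], ord$edge[, 1])
  # process each internal node only after all its children: order nodes by
  # their last occurrence as a parent in the postorder edge list
  parents <- ord$edge[, 1]
  node_order <- rev(unique(rev(parents)))
  for (j in seq_len(ncol(aln))) {
    sets <- vector("list", nt + sub$Nnode)
    for (i in seq_len(nt)) {
      r <- sub_aln[i, j]
      sets[[i]] <- if (r %in% full) r else full
    }
    ch <- 0L
    for (nd in node_order) {
      kids <- node_children[[as.character(nd)]]
      s <- sets[[kids[[1]]]]
      for (k in kids[-1]) {
        inter <- intersect(s, sets[[k]])
        if (length(inter)) {
          s <- inter
        } else {
          s <- union(s, sets[[k]])
          ch <- ch + 1L
        }
      }
      sets[[nd]] <- s
    }
    counts[[j]] <- ch
  }
  list(counts = counts, tree_length = sum(sub$edge.length), clade = clade)
}

#' Type I functional divergence between two clades
#'
#' Detects site-specific substitution-rate shifts between duplicate clades
#' from per-site parsimony counts. Site rates are gamma-distributed
#' (exponential at the default shape 1) and per-site counts are Poisson
#' with mean rate x clade tree length. With probability `1 - theta` a
#' site's rate is shared between the clades; with probability `theta` the
#' two clades draw independent rates. Both marginal likelihoods are closed
#' form (gamma-Poisson), and `theta` plus the rate-scale parameter are
#' estimated by maximum likelihood; the per-site posterior probability of
#' the divergent component is reported and sites are flagged at
#' `pp_cutoff`.
#'
#' @param counts_a,counts_b `fitch_counts()` results for the two clades
#'   (same columns).
#' @param pp_cutoff Posterior-probability cutoff for flagged sites.
#' @param gamma_shape Shape of the site-rate distribution.
#' @return List with `theta`, `theta_se`, `pp` (per-site posteriors),
#'   `flagged` (column indices with `pp >= pp_cutoff`), `pp_cutoff`,
#'   `rate_scale`.
#' @export
type1_divergence <- function(counts_a, counts_b, pp_cutoff = 0.90,
                             gamma_shape = 1) {
  xa <- counts_a$counts; xb <- counts_b$counts
  if (length(xa) != length(xb)) {
    stop("clades must share the same alignment columns", call. = FALSE)
  }
  ta <- counts_a$tree_length; tb <- counts_b$tree_length
  a <- gamma_shape
  # log marginal of a Poisson(x; r*t) count with r ~ Gamma(a, rate = b):
  # negative binomial with size a, prob b/(t+b)
  lmarg <- function(x, t, b) {
    lgamma(x + a) - lgamma(a) - lgamma(x + 1) +
      a * log(b / (t + b)) + x * log(t / (t + b))
  }
  # shared rate: x_a + independent Poisson pieces share one r
  lshared <- function(b) {
    lgamma(xa + xb + a) - lgamma(a) - lgamma(xa + 1) - lgamma(xb + 1) +
      a * log(b / (ta + tb + b)) + xa * log(ta / (ta + tb + b)) +
      xb * log(tb / (ta + tb + b))
  }
  lindep <- function(b) lmarg(xa, ta, b) + lmarg(xb, tb, b)
  nll <- function(par) {
    theta <- stats::plogis(par[[1]]); b <- exp(par[[2]])
    l0 <- lshared(b); l1 <- lindep(b)
    m <- pmax(l0, l1)
    -sum(m + log((1 - theta) * exp(l0 - m) + theta * exp(l1 - m)))
  }
  # moment-style init for the rate scale: mean count ~ a * t / b
  b0 <- a * (ta + tb) / max(mean(xa + xb), 0.1)
  fit <- stats::optim(c(0, log(b0)), nll, method = "BFGS", hessian = TRUE)
  theta <- stats::plogis(fit$par[[1]])
  b <- exp(fit$par[[2]])
  # delta-method SE on theta from the logit-scale Hessian
  se <- tryCatch({
    vc <- solve(fit$hessian)
    if (is.finite(vc[1, 1]) && vc[1, 1] > 0) {
      sqrt(vc[1, 1]) * theta * (1 - theta)
    } else {
      NA_real_   # boundary estimate: information matrix near-singular
    }
  }, error = function(e) NA_real_)
  l0 <- lshared(b); l1 <- lindep(b)
  m <- pmax(l0, l1)
  pp <- theta * exp(l1 - m) /
    ((1 - theta) * exp(l0 - m) + theta * exp(l1 - m))
  list(theta = theta, theta_se = se, pp = pp,
       flagged = which(pp >= pp_cutoff), pp_cutoff = pp_cutoff,
       rate_scale = b)
}

#' Type II (fixed radical) divergent sites between two clades
#'
#' Columns where each clade is fixed (one residue at frequency
#' `>= fixation_threshold` among non-gap rows), the fixed residues differ,
#' and they belong to different physicochemical classes. Symmetric in the
#' two clades; empty when the clades are identical.
#'
#' @param aln_a,aln_b Alignment matrices sharing the same column frame.
#' @param classes Physicochemical partition.
#' @param fixation_threshold Minimum within-clade frequency to call a
#'   residue fixed.
#' @return Integer vector of column indices.
#' @export
type2_sites <- function(aln_a, aln_b, classes = residue_classes(),
                        fixation_threshold = 0.95) {
  if (ncol(aln_a) != ncol(aln_b)) {
    stop("alignments must share the same column frame", call. = FALSE)
  }
  fixed_residue <- function(col) {
    res <- col[col %in% AA]
    if (!length(res)) return(NA_character_)
    tab <- table(res)
    if (max(tab) / length(res) >= fixation_threshold) {
      names(tab)[which.max(tab)]
    } else NA_character_
  }
  out <- integer(0)
  for (j in seq_len(ncol(aln_a))) {
    fa <- fixed_residue(aln_a[, j]); fb <- fixed_residue(aln_b[, j])
    if (is.na(fa) || is.na(fb) || fa == fb) next
    ca <- residue_class_of(fa, classes); cb <- residue_class_of(fb, classes)
    if (!is.na(ca) && !is.na(cb) && ca != cb) out <- c(out, j)
  }
  out
}

#' Per-domain divergence ratios within a clade
#'
#' For each named domain (disjoint column sets), the mean pairwise
#' Poisson-corrected distance among the clade's rows on that domain's
#' columns, divided by the mean over the *other* domains (leave-one-out,
#' so the baseline is not contaminated by the domain under test). A ratio
#' above `degradation_ratio_threshold` marks the domain "degraded-like"
#' (its sequences diverge disproportionately, the signature of a domain
#' under relaxed constraint). When all distances are zero the ratio is 1
#' by convention.
#'
#' @param aln Alignment matrix.
#' @param clade Row ids to analyse.
#' @param domain_columns Named list of disjoint column-index vectors.
#' @param degradation_ratio_threshold Flagging threshold.
#' @return Data frame with `domain`, `mean_distance`, `ratio`,
#'   `degraded_like`.
#' @export
domain_divergence_ratio <- function(aln, clade, domain_columns,
                                    degradation_ratio_threshold = 2.0) {
  if (length(domain_columns) < 2) {
    stop("need at least two named domains", call. = FALSE)
  }
  if (any(lengths(domain_columns) == 0)) {
    stop("empty domain column set", call. = FALSE)
  }
  all_cols <- unlist(domain_columns)
  if (anyDuplicated(all_cols)) stop("domain column sets must be disjoint",
                                    call. = FALSE)
  sub <- aln[clade, , drop = FALSE]
  dist_mean <- vapply(domain_columns, function(cols) {
    block <- alignment(unclass(sub)[, cols, drop = FALSE])
    D <- suppressWarnings(poisson_distance(block))
    mean(D[upper.tri(D)])
  }, numeric(1))
  ratio <- vapply(seq_along(dist_mean), function(i) {
    base <- mean(dist_mean[-i])
    if (base == 0) {
      if (dist_mean[[i]] == 0) 1 else Inf
    } else {
      dist_mean[[i]] / base
    }
  }, numeric(1))
  data.frame(domain = names(domain_columns), mean_distance = dist_mean,
             ratio = ratio,
             degraded_like = ratio > degradation_ratio_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call the synthetase specificity motif of an aligned sequence
#'
#' The G-nucleotide specificity motif of the synthetase domain spans four
#' alignment columns: `E-x-D-D` confers GDP preference (the RelA-type
#' acidic motif), `R-x-K-D` GTP preference (the Rel/SpoT-type basic
#' motif); anything else is `unknown`.
#'
#' @param aligned_seq Aligned residue string (or character vector).
#' @param motif_columns Four column indices in the alignment frame.
#' @return `"GDP_type"`, `"GTP_type"` or `"unknown"`.
#' @export
specificity_motif <- function(aligned_seq, motif_columns) {
  chars <- if (length(aligned_seq) == 1) strsplit(aligned_seq, "")[[1]]
           else aligned_seq
  if (length(motif_columns) != 4) {
    stop("motif_columns must give exactly 4 columns", call. = FALSE)
  }
  if (any(motif_columns < 1 | motif_columns > length(chars))) {
    stop("motif columns outside alignment", call. = FALSE)
  }
  m <- toupper(chars[motif_columns])
  if (m[[1]] == "E" && m[[3]] == "D" && m[[4]] == "D") return("GDP_type")
  if (m[[1]] == "R" && m[[3]] == "K" && m[[4]] == "D") return("GTP_type")
  "unknown"
}
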