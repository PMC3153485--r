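# Independent brute-force oracles used across tests. These enumerate the
# same probabilistic models as the package code but share no implementation
# with it.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# exhaustive path enumeration over the local profile grammar: entry B->M_k
# uniform, exit M_k->E with prob 1/(M-k+1) (remaining mass on M/I/D moves),
# delete chains may end at D_M (exit prob 1); flanking residues free
brute_hmm_scores <- function(hmm, seq) {
  x <- strsplit(toupper(seq), "")[[1]]
  xi <- match(x, AA20)
  L <- length(xi); M <- hmm$M
  em <- function(k, i) {
    if (is.na(xi[i])) return(0)
    log2(hmm$match_emissions[k, xi[i]] / hmm$background[xi[i]])
  }
  iem <- function(i) {
    if (is.na(xi[i])) return(0)
    log2(hmm$insert_emissions[xi[i]] / hmm$background[xi[i]])
  }
  q <- 1 / (M - seq_len(M) + 1)
  scores <- c()
  rec <- function(state, k, i, lo) {
    if (state == "M") {
      scores <<- c(scores, lo + log2(q[k]))
      if (k < M) {
        if (i < L) rec("M", k + 1, i + 1,
                       lo + log2((1 - q[k]) * hmm$t_mm[k]) + em(k + 1, i + 1))
        if (i < L) rec("I", k, i + 1,
                       lo + log2((1 - q[k]) * hmm$t_mi[k]) + iem(i + 1))
        rec("D", k + 1, i, lo + log2((1 - q[k]) * hmm$t_md[k]))
      }
    } else if (state == "I") {
      if (i < L) {
        rec("M", k + 1, i + 1, lo + log2(hmm$t_im[k]) + em(k + 1, i + 1))
        rec("I", k, i + 1, lo + log2(hmm$t_ii[k]) + iem(i + 1))
      }
    } else {
      if (k == M) {
        scores <<- c(scores, lo)
      } else {
        if (i < L) rec("M", k + 1, i + 1,
                       lo + log2(hmm$t_dm[k]) + em(k + 1, i + 1))
        rec("D", k + 1, i, lo + log2(hmm$t_dd[k]))
      }
    }
  }
  for (s in seq_len(L)) {
    for (k0 in seq_len(M)) rec("M", k0, s, -log2(M) + em(k0, s))
  }
  m <- max(scores)
  list(viterbi = m, forward = m + log2(sum(2^(scores - m))))
}

# random valid toy profile HMM (uniform background)
random_toy_hmm <- function(M, seed) {
  set.seed(seed)
  rdir <- function(n) { x <- stats::rgamma(n, 1); x / sum(x) }
  hmm <- structure(list(
    name = "toy", kind = "domain", M = M,
    match_emissions = t(vapply(seq_len(M), function(i) rdir(20),
                               numeric(20))),
    insert_emissions = rdir(20),
    background = rep(1 / 20, 20),
    t_mm = numeric(0), t_mi = numeric(0), t_md = numeric(0),
    t_im = numeric(0), t_ii = numeric(0),
    t_dm = numeric(0), t_dd = numeric(0),
    match_columns = seq_len(M), calibration = NULL),
    class = "profile_hmm")
  colnames(hmm$match_emissions) <- AA20
  if (M > 1) {
    tm <- t(vapply(seq_len(M - 1), function(i) rdir(3), numeric(3)))
    ti <- t(vapply(seq_len(M - 1), function(i) rdir(2), numeric(2)))
    td <- t(vapply(seq_len(M - 1), function(i) rdir(2), numeric(2)))
    hmm$t_mm <- tm[, 1]; hmm$t_mi <- tm[, 2]; hmm$t_md <- tm[, 3]
    hmm$t_im <- ti[, 1]; hmm$t_ii <- ti[, 2]
    hmm$t_dm <- td[, 1]; hmm$t_dd <- td[, 2]
  }
  hmm
}

# brute-force minimum substitution count for one column on a binary tree:
# minimise over all internal-node labelings; leaves with missing data can
# take any state at no cost (equivalent to excluding them)
brute_fitch_column <- function(tree, states) {
  nt <- length(tree$tip.label)
  obs <- unique(states[!is.na(states)])
  if (length(obs) <= 1) return(0L)
  internal <- nt + seq_len(tree$Nnode)
  grids <- rep(list(obs), tree$Nnode)
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    lab <- character(nt + tree$Nnode)
    lab[internal] <- unlist(combos[r, ])
    lab[seq_len(nt)] <- states
    ch <- 0L
    for (e in seq_len(nrow(tree$edge))) {
      a <- lab[tree$edge[e, 1]]; b <- lab[tree$edge[e, 2]]
      if (!is.na(b) && a != b) ch <- ch + 1L
    }
    best <- min(best, ch)
  }
  as.integer(best)
}

# random binary tree with exponential branch lengths; its cophenetic
# matrix is additive by construction
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::rexp(length(tr$edge.length), 2) + 0.05
  tr
}

random_alignment <- function(n, L, seed, gap_frac = 0) {
  set.seed(seed)
  rows <- vapply(seq_len(n), function(i) {
    chars <- sample(AA20, L, replace = TRUE)
    if (gap_frac > 0) {
      g <- stats::runif(L) < gap_frac
      if (all(g)) g[1] <- FALSE
      chars[g] <- "-"
    }
    paste(chars, collapse = "")
  }, character(1))
  alignment(stats::setNames(rows, paste0("s", seq_len(n))))
}
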