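#' Synthetic protein-superfamily simulation
#'
#' Generates superfamilies with known truth: `k` subgroups descend from a
#' common ancestor (each subgroup root evolves from the family root along a
#' backbone branch, then members evolve along a shared genome tree), with
#' two catalytic domains (HD-like hydrolase, SYNTH-like synthetase) plus
#' optional C-terminal domains. Subgroup events model the biology of the
#' RSH superfamily: whole-domain loss (SAS/SAH analogues), domain
#' degradation (elevated substitution rate, the inactive-hydrolase
#' analogue), site-specific rate shifts between clades (type I divergence),
#' and fixed radical substitutions at specificity-motif columns (type II,
#' EXDD-vs-RXKD-like). Decoy proteins (i.i.d. background residues) and
#' short fragments exercise specificity and length filtering. There is no
#' indel process within domains, so the true per-domain alignments are
#' exact.
#'
#' @name synthdata
NULL

#' Simulate a birth-process (Yule) genome tree
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param birth_rate Speciation rate.
#' @param seed Integer seed (deterministic per seed).
#' @return Ultrametric binary `phylo` tree with tips `t1..tn`.
#' @export
simulate_tree <- function(n_leaves, birth_rate = 1, seed = 1) {
  if (n_leaves < 2) stop("need at least 2 leaves", call. = FALSE)
  with_local_seed(seed, {
    if (n_leaves == 2) {
      t <- stats::rexp(1, birth_rate)
      ape::read.tree(text = sprintf("(t1:%.8f,t2:%.8f);", t, t))
    } else {
      ape::rphylo(n_leaves, birth = birth_rate, death = 0)
    }
  })
}

# rescale branch lengths so the maximum root-to-tip depth equals `depth`
scale_tree_depth <- function(tree, depth) {
  cur <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * depth / cur
  tree
}

# class-biased replacement matrix: within-class moves `bias` times more
# likely than between-class; no self-replacement
replacement_matrix <- function(bias = 4, classes = residue_classes()) {
  cls <- residue_class_of(AA, classes)
  W <- outer(cls, cls, function(a, b) ifelse(a == b, bias, 1))
  diag(W) <- 0
  W / rowSums(W)
}

# apply `n` sequential substitutions to residue index `cur`
mutate_site <- function(cur, n, R) {
  for (s in seq_len(n)) cur <- sample.int(20, 1, prob = R[cur, ])
  cur
}

# evolve integer-encoded sequence along one branch; returns new sequence
# and number of substitution events per site
evolve_branch <- function(seq_idx, rates, t, R) {
  n <- stats::rpois(length(seq_idx), rates * t)
  hot <- which(n > 0)
  for (i in hot) seq_idx[[i]] <- mutate_site(seq_idx[[i]], n[[i]], R)
  list(seq = seq_idx, n_subs = n)
}

#' Evolve a root sequence along a tree
#'
#' Site `i` on a branch of length `t` receives `Poisson(rates[i] * t)`
#' substitutions; each substitution replaces the residue via the
#' class-biased replacement distribution (within-class moves
#' `replacement_bias` times more likely than between-class). No indels.
#'
#' @param root_seq Residue string (or character vector) at the root.
#' @param tree `phylo` tree with branch lengths.
#' @param site_rates Non-negative rates, one per site.
#' @param seed Integer seed.
#' @param replacement_bias Within-class weighting.
#' @return Alignment matrix with one row per leaf; attribute `n_subs`
#'   holds the total realized substitution count per site over the tree.
#' @export
evolve_alignment <- function(root_seq, tree, site_rates, seed = 1,
                             replacement_bias = 4) {
  root <- if (length(root_seq) == 1) strsplit(root_seq, "")[[1]] else root_seq
  if (length(root) != length(site_rates)) {
    stop("root profile length must equal the number of site rates",
         call. = FALSE)
  }
  if (any(site_rates < 0)) stop("site rates must be non-negative",
                                call. = FALSE)
  R <- replacement_matrix(replacement_bias)
  root_idx <- match(toupper(root), AA)
  nt <- length(tree$tip.label)
  with_local_seed(seed, {
    node_seq <- vector("list", nt + tree$Nnode)
    node_seq[[nt + 1L]] <- root_idx
    n_subs <- numeric(length(root_idx))
    ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      ev <- evolve_branch(node_seq[[parent]], site_rates,
                          ord$edge.length[[e]], R)
      node_seq[[child]] <- ev$seq
      n_subs <- n_subs + ev$n_subs
    }
    mat <- do.call(rbind, lapply(seq_len(nt), function(i) AA[node_seq[[i]]]))
    rownames(mat) <- tree$tip.label
    aln <- alignment(mat)
    attr(aln, "n_subs") <- n_subs
    aln
  })
}

#' Simulation configuration
#'
#' @param n_genomes Number of genomes.
#' @param domains Named list of domain specs:
#'   `list(length=, mean_rate=, gamma_shape=)`.
#' @param subgroups Named list of subgroup specs:
#'   `list(domains = c(...), class = "long"|"SAS"|"SAH", events = list(...),
#'   present = integer genome indices or NULL for all)`. Events are lists
#'   with `type` in `drop_domain` (expressed by omitting the domain from
#'   `domains`), `degrade_domain` (`domain`, `factor`), `rate_shift`
#'   (`domain`, `fraction`, `factor`), `fixed_substitution` (`domain`,
#'   `column`, `residue`).
#' @param conserved_in Optional list of
#'   `list(domain=, columns=, subgroups=)` blocks: columns held invariant
#'   (rate 0) within the named subgroups and along their backbones, and
#'   given a high floor rate elsewhere, so they are conserved in exactly
#'   that group of subgroups.
#' @param backbone_length Branch length from family root to each subgroup
#'   root (substitutions/site at rate 1).
#' @param genome_tree_depth Root-to-tip depth of the within-subgroup tree.
#' @param birth_rate Genome-tree speciation rate.
#' @param decoys_per_genome Unrelated background proteins per genome.
#' @param decoy_length_range Length range for decoys.
#' @param fragment_fraction Fraction of family proteins additionally
#'   emitted as a truncated (<100 aa) copy.
#' @param replacement_bias Within-class replacement weighting.
#' @param seed Integer master seed.
#' @return Validated config list of class `sim_config`.
#' @export
sim_config <- function(n_genomes, domains, subgroups,
                       conserved_in = list(),
                       backbone_length = 0.6, genome_tree_depth = 0.15,
                       birth_rate = 1, decoys_per_genome = 3,
                       decoy_length_range = c(120, 400),
                       fragment_fraction = 0, replacement_bias = 4,
                       seed = 1) {
  cfg <- list(n_genomes = n_genomes, domains = domains,
              subgroups = subgroups, conserved_in = conserved_in,
              backbone_length = backbone_length,
              genome_tree_depth = genome_tree_depth,
              birth_rate = birth_rate,
              decoys_per_genome = decoys_per_genome,
              decoy_length_range = decoy_length_range,
              fragment_fraction = fragment_fraction,
              replacement_bias = replacement_bias, seed = seed)
  for (d in names(domains)) {
    sp <- domains[[d]]
    if (sp$length < 1 || sp$mean_rate <= 0 || sp$gamma_shape <= 0) {
      stop(sprintf("invalid spec for domain '%s'", d), call. = FALSE)
    }
  }
  if (fragment_fraction < 0 || fragment_fraction >= 1) {
    stop("fragment_fraction must lie in [0, 1)", call. = FALSE)
  }
  for (sg in names(subgroups)) {
    sp <- subgroups[[sg]]
    if (!all(sp$domains %in% names(domains))) {
      stop(sprintf("subgroup '%s' references undeclared domain", sg),
           call. = FALSE)
    }
    for (ev in sp$events %||% list()) {
      if (!ev$domain %in% names(domains)) {
        stop(sprintf("event in subgroup '%s' references undeclared domain '%s'",
                     sg, ev$domain), call. = FALSE)
      }
      if (!is.null(ev$factor) && ev$factor <= 0) {
        stop("event rate factor must be positive", call. = FALSE)
      }
      if (!is.null(ev$fraction) &&
          (ev$fraction < 0 || ev$fraction > 1)) {
        stop("event fraction must lie in [0, 1]", call. = FALSE)
      }
    }
  }
  structure(cfg, class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference superfamily configuration
#'
#' The study conditions used throughout the package's validation: 20
#' genomes, 6 subgroups — three long (bifunctional) subgroups of which one
#' (`LongA`, the RelA analogue) carries a degraded HD domain and the
#' EXDD-type specificity motif while the others carry RXKD; two SYNTH-only
#' (SAS) subgroups; one HD-only (SAH) subgroup — plus 3 decoys per genome
#' and 10% truncated fragments. Domain lengths: SYNTH 113 (the mean length
#' of the synthetase domain), HD 168, TGS 60, ACT 60. Ten SYNTH columns are
#' conserved only in the long subgroups (inter-domain crosstalk analogue),
#' and `LongC` carries a 15% / 5x rate shift in SYNTH relative to the other
#' clades. Genome `g20` is engineered to carry only a SAS, violating the
#' synthetase-without-hydrolase complement rule.
#'
#' @param seed Master seed.
#' @param n_genomes Number of genomes.
#' @return A `sim_config`.
#' @export
reference_config <- function(seed = 42, n_genomes = 20) {
  motif_cols <- c(90, 91, 92, 93)
  exdd <- c("E", "F", "D", "D")
  rxkd <- c("R", "F", "K", "D")
  fix <- function(res) {
    lapply(seq_along(motif_cols), function(i) {
      list(type = "fixed_substitution", domain = "SYNTH",
           column = motif_cols[[i]], residue = res[[i]])
    })
  }
  sim_config(
    n_genomes = n_genomes,
    domains = list(
      HD    = list(length = 168, mean_rate = 1, gamma_shape = 0.5),
      SYNTH = list(length = 113, mean_rate = 1, gamma_shape = 0.5),
      TGS   = list(length = 60,  mean_rate = 1, gamma_shape = 0.5),
      ACT   = list(length = 60,  mean_rate = 1, gamma_shape = 0.5)
    ),
    subgroups = list(
      LongA = list(domains = c("HD", "SYNTH", "TGS", "ACT"), class = "long",
                   present = 1:(n_genomes - 1),
                   events = c(list(list(type = "degrade_domain",
                                        domain = "HD", factor = 4)),
                              fix(exdd))),
      LongB = list(domains = c("HD", "SYNTH", "TGS", "ACT"), class = "long",
                   present = 1:(n_genomes - 1),
                   events = fix(rxkd)),
      LongC = list(domains = c("HD", "SYNTH", "TGS", "ACT"), class = "long",
                   present = 1:(n_genomes - 1),
                   events = c(list(list(type = "rate_shift",
                                        domain = "SYNTH", fraction = 0.15,
                                        factor = 5)),
                              fix(rxkd))),
      # SAS1 is present in every genome; the last genome carries nothing
      # else, engineering a synthetase-without-hydrolase rule violation
      SAS1  = list(domains = "SYNTH", class = "SAS", events = list()),
      SAS2  = list(domains = "SYNTH", class = "SAS", events = list(),
                   present = 1:(n_genomes - 1)),
      SAH1  = list(domains = "HD", class = "SAH", events = list(),
                   present = 1:(n_genomes - 1))
    ),
    conserved_in = list(
      list(domain = "SYNTH", columns = c(10, 21, 33, 45, 52, 64, 71, 83,
                                         100, 108),
           subgroups = c("LongA", "LongB", "LongC"))
    ),
    backbone_length = 0.6,
    genome_tree_depth = 0.15,
    decoys_per_genome = 3,
    fragment_fraction = 0.1,
    seed = seed
  )
}

#' Simulate a pair of duplicate clades with site-specific rate shifts
#'
#' The validation scenario for type I functional-divergence detection: two
#' clades descend from one root sequence; a fraction of sites evolve at a
#' multiplied rate in clade B only. Clade sizes and depths default to the
#' regime where parsimony counts retain the rate signal (two dozen leaves,
#' moderate branch lengths); deep sparse clades saturate parsimony and
#' wash the shift out.
#'
#' @param seed Integer seed.
#' @param n_leaves Leaves per clade.
#' @param n_columns Alignment columns.
#' @param fraction Fraction of sites shifted.
#' @param multiplier Rate multiplier in clade B at shifted sites.
#' @param depth Root-to-tip depth of each clade tree.
#' @param gamma_shape Site-rate gamma shape.
#' @return List with `tree_a`, `tree_b`, `aln_a`, `aln_b`, and
#'   `shifted` (true shifted-column indices).
#' @export
simulate_rate_shift_pair <- function(seed = 1, n_leaves = 24,
                                     n_columns = 200, fraction = 0.15,
                                     multiplier = 5, depth = 0.35,
                                     gamma_shape = 1) {
  prep <- with_local_seed(seed, {
    rates <- stats::rgamma(n_columns, gamma_shape, gamma_shape)
    shifted <- sort(sample.int(n_columns, round(fraction * n_columns)))
    root <- sample(AA, n_columns, replace = TRUE)
    list(rates = rates, shifted = shifted, root = root)
  })
  rates_b <- prep$rates
  rates_b[prep$shifted] <- rates_b[prep$shifted] * multiplier
  tr_a <- scale_tree_depth(simulate_tree(n_leaves, seed = seed * 2 + 1),
                           depth)
  tr_b <- scale_tree_depth(simulate_tree(n_leaves, seed = seed * 2 + 2),
                           depth)
  tr_a$tip.label <- paste0("a", seq_len(n_leaves))
  tr_b$tip.label <- paste0("b", seq_len(n_leaves))
  list(tree_a = tr_a, tree_b = tr_b,
       aln_a = evolve_alignment(prep$root, tr_a, prep$rates,
                                seed = seed * 3 + 1),
       aln_b = evolve_alignment(prep$root, tr_b, rates_b,
                                seed = seed * 3 + 2),
       shifted = prep$shifted)
}

#' Simulate a protein superfamily with known truth
#'
#' @param config A `sim_config`.
#' @param out_dir Optional directory; when given, writes one FASTA per
#'   genome, `truth.json`, `true_tree.nwk` and `true_aln_<domain>.afa`.
#' @return List with `proteomes` (named list of sequence-record frames, one
#'   per genome) and `truth` (see Details). Truth components: `proteins`
#'   (seq_id, genome_id, subgroup, class, is_decoy, is_fragment, length),
#'   `architecture` (seq_id, domain, start, end, degraded), `domain_alns`
#'   (true per-domain alignments), `tree` (true protein tree),
#'   `shifted_sites`, `fixed_substitutions`, `conserved_in`.
#' @export
simulate_superfamily <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  genomes <- sprintf("g%02d", seq_len(cfg$n_genomes))

  gtree <- simulate_tree(cfg$n_genomes, cfg$birth_rate,
                         seed = cfg$seed + 1000L)
  gtree <- scale_tree_depth(gtree, cfg$genome_tree_depth)
  gtree$tip.label <- genomes

  # family root sequence and site rates per domain
  roots <- list(); rates <- list()
  with_local_seed(cfg$seed + 2000L, {
    for (d in names(cfg$domains)) {
      sp <- cfg$domains[[d]]
      dominant <- sample(AA, sp$length, replace = TRUE)
      pref <- function(dom) {
        p <- rep(0.3 / 19, 20); p[match(dom, AA)] <- 0.7; p
      }
      roots[[d]] <- vapply(dominant, function(dom) {
        sample(AA, 1, prob = pref(dom))
      }, character(1))
      rates[[d]] <- stats::rgamma(sp$length, shape = sp$gamma_shape,
                                  rate = sp$gamma_shape) * sp$mean_rate
    }
  })

  shifted <- list(); fixed <- list()
  domain_rows <- lapply(cfg$domains, function(d) list())  # per-domain leaf rows
  prot_rows <- list(); arch_rows <- list()
  sub_leaf_trees <- character(0)

  sgi <- 0L
  for (sg in names(cfg$subgroups)) {
    sgi <- sgi + 1L
    sp <- cfg$subgroups[[sg]]
    present <- genomes[sp$present %||% seq_len(cfg$n_genomes)]
    sub_tree <- if (length(present) < cfg$n_genomes) {
      ape::keep.tip(gtree, present)
    } else gtree
    degraded_domains <- character(0)
    leaf_by_domain <- list()
    for (d in sp$domains) {
      r <- rates[[d]]
      backbone_r <- r
      ev_fix <- list()
      for (ev in sp$events %||% list()) {
        if (ev$domain != d) next
        if (ev$type == "degrade_domain") {
          r <- r * ev$factor; backbone_r <- backbone_r * ev$factor
          degraded_domains <- c(degraded_domains, d)
        } else if (ev$type == "rate_shift") {
          ncol_shift <- round(ev$fraction * length(r))
          cols <- with_local_seed(cfg$seed + 3000L + sgi, {
            sort(sample.int(length(r), ncol_shift))
          })
          r[cols] <- r[cols] * ev$factor
          shifted[[length(shifted) + 1]] <- list(subgroup = sg, domain = d,
                                                 columns = cols,
                                                 factor = ev$factor)
        } else if (ev$type == "fixed_substitution") {
          ev_fix[[length(ev_fix) + 1]] <- ev
        }
      }
      for (blk in cfg$conserved_in) {
        if (blk$domain != d) next
        if (sg %in% blk$subgroups) {
          r[blk$columns] <- 0; backbone_r[blk$columns] <- 0
        } else {
          # the truth label promises these columns are conserved ONLY in
          # the listed subgroups: give everyone else a floor rate high
          # enough that conservation there is structurally impossible,
          # not left to the luck of the gamma draw
          r[blk$columns] <- pmax(r[blk$columns], 8)
          backbone_r[blk$columns] <- pmax(backbone_r[blk$columns], 8)
        }
      }
      for (ev in ev_fix) {
        r[ev$column] <- 0; backbone_r[ev$column] <- 0
      }
      # subgroup root: family root evolved along the backbone branch
      bb <- ape::read.tree(text = sprintf("(x:%.8f,y:0);",
                                          cfg$backbone_length))
      bb_aln <- evolve_alignment(roots[[d]], bb, backbone_r,
                                 seed = cfg$seed + 4000L + sgi * 37L +
                                   match(d, names(cfg$domains)),
                                 replacement_bias = cfg$replacement_bias)
      sub_root <- unclass(bb_aln)["x", ]
      for (ev in ev_fix) {
        sub_root[[ev$column]] <- ev$residue
        fixed[[length(fixed) + 1]] <- list(subgroup = sg, domain = d,
                                           column = ev$column,
                                           residue = ev$residue)
      }
      leaf <- evolve_alignment(sub_root, sub_tree, r,
                               seed = cfg$seed + 5000L + sgi * 37L +
                                 match(d, names(cfg$domains)),
                               replacement_bias = cfg$replacement_bias)
      leaf_by_domain[[d]] <- unclass(leaf)
    }
    # assemble proteins, record truth
    ids <- paste(present, sg, sep = "_")
    sub_tree_named <- sub_tree
    sub_tree_named$tip.label <- paste(sub_tree$tip.label, sg, sep = "_")
    sub_leaf_trees <- c(sub_leaf_trees,
                        sub(";$", "",
                            ape::write.tree(sub_tree_named, digits = 10)))
    for (gi in seq_along(present)) {
      g <- present[[gi]]
      id <- paste(g, sg, sep = "_")
      parts <- character(0); pos <- 0L
      for (d in sp$domains) {
        row <- leaf_by_domain[[d]][g, , drop = TRUE]
        seg <- paste(row, collapse = "")
        arch_rows[[length(arch_rows) + 1]] <- data.frame(
          seq_id = id, domain = d, start = pos + 1L,
          end = pos + nchar(seg),
          degraded = d %in% degraded_domains, stringsAsFactors = FALSE)
        pos <- pos + nchar(seg)
        parts <- c(parts, seg)
        domain_rows[[d]][[id]] <- row
      }
      resid <- paste(parts, collapse = "")
      prot_rows[[length(prot_rows) + 1]] <- data.frame(
        seq_id = id, genome_id = g, subgroup = sg, class = sp$class,
        is_decoy = FALSE, is_fragment = FALSE, length = nchar(resid),
        residues = resid, stringsAsFactors = FALSE)
    }
  }
  proteins <- do.call(rbind, prot_rows)

  # decoys
  with_local_seed(cfg$seed + 6000L, {
    for (g in genomes) {
      for (k in seq_len(cfg$decoys_per_genome)) {
        len <- sample(seq(cfg$decoy_length_range[[1]],
                          cfg$decoy_length_range[[2]]), 1)
        resid <- paste(sample(AA, len, replace = TRUE), collapse = "")
        proteins <- rbind(proteins, data.frame(
          seq_id = sprintf("%s_decoy%d", g, k), genome_id = g,
          subgroup = NA_character_, class = "none", is_decoy = TRUE,
          is_fragment = FALSE, length = len, residues = resid,
          stringsAsFactors = FALSE))
      }
    }
  })

  # truncated fragment copies of family proteins
  fam_idx <- which(!proteins$is_decoy)
  n_frag <- floor(cfg$fragment_fraction * length(fam_idx))
  if (n_frag > 0) {
    with_local_seed(cfg$seed + 7000L, {
      pick <- sample(fam_idx, n_frag)
      for (i in pick) {
        len <- sample(60:99, 1)
        proteins <- rbind(proteins, data.frame(
          seq_id = paste0(proteins$seq_id[[i]], "_frag"),
          genome_id = proteins$genome_id[[i]],
          subgroup = proteins$subgroup[[i]],
          class = proteins$class[[i]], is_decoy = FALSE,
          is_fragment = TRUE, length = len,
          residues = substr(proteins$residues[[i]], 1, len),
          stringsAsFactors = FALSE))
      }
    })
  }

  true_tree <- ape::read.tree(text = paste0(
    "(", paste(sprintf("%s:%.8f", sub_leaf_trees, cfg$backbone_length),
               collapse = ","), ");"))

  domain_alns <- lapply(names(cfg$domains), function(d) {
    rows <- domain_rows[[d]]
    if (!length(rows)) return(NULL)
    mat <- do.call(rbind, rows)
    rownames(mat) <- names(rows)
    alignment(mat)
  })
  names(domain_alns) <- names(cfg$domains)
  domain_alns <- Filter(Negate(is.null), domain_alns)

  proteomes <- lapply(split(proteins, proteins$genome_id), function(df) {
    seq_records(df$seq_id, df$residues, organism = df$genome_id)
  })
  proteomes <- proteomes[genomes]

  truth <- list(
    proteins = proteins[, setdiff(names(proteins), "residues")],
    architecture = do.call(rbind, arch_rows),
    domain_alns = domain_alns,
    tree = true_tree,
    shifted_sites = shifted,
    fixed_substitutions = fixed,
    conserved_in = cfg$conserved_in,
    config_seed = cfg$seed
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in names(proteomes)) {
      write_fasta(proteomes[[g]], file.path(out_dir, paste0(g, ".fasta")))
    }
    write_newick(true_tree, file.path(out_dir, "true_tree.nwk"))
    for (d in names(domain_alns)) {
      write_alignment(domain_alns[[d]],
                      file.path(out_dir, sprintf("true_aln_%s.afa", d)))
    }
    tr <- truth[setdiff(names(truth), c("domain_alns", "tree"))]
    jsonlite::write_json(tr, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(proteomes = proteomes, truth = truth)
}
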