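#' Pipeline configuration
#'
#' Thresholds and knobs for the iterative classification pipeline. The
#' staged E-value gates follow the classic iterative-search design: a permissive
#' gathering threshold (1e-2) collects candidates, a stricter phylogeny
#' gate (1e-5) selects reliably alignable sequences for tree building, and
#' asymmetric final per-domain thresholds (SYNTH 1e-4, HD 1e-5) remove
#' spurious domain hits before architectures are called.
#'
#' @param gather_threshold Gathering E-value gate.
#' @param phylo_threshold E-value gate for phylogenetic analysis.
#' @param final_thresholds Named per-domain final E-value gates.
#' @param default_final_threshold Final gate for domains not named above.
#' @param min_fragment_length Sequences shorter than this are dropped.
#' @param min_subgroup_size Minimum taxa for an emitted subgroup (and for
#'   building a subgroup HMM).
#' @param min_support Minimum bootstrap percentage for a subgroup clade.
#' @param consensus_threshold Percentage-similarity consensus threshold.
#' @param pp_cutoff Posterior-probability cutoff for type I sites.
#' @param max_iterations Maximum refinement rounds.
#' @param min_model_span Minimum model-span fraction for a hit.
#' @param n_bootstrap Bootstrap replicates for subgroup supports.
#' @param compactness Subgroup compactness multiplier (see
#'   [extract_subgroups()]).
#' @param degradation_ratio_threshold Domain-divergence flag threshold.
#' @param activity_ratio_threshold Bit-density ratio below which a domain
#'   hit is called degraded.
#' @param activity_min_span Span fraction below which a hit is degraded.
#' @param seed Master seed for calibration and bootstrap.
#' @return Validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(gather_threshold = 1e-2,
                            phylo_threshold = 1e-5,
                            final_thresholds = c(SYNTH = 1e-4, HD = 1e-5),
                            default_final_threshold = 1e-4,
                            min_fragment_length = 100,
                            min_subgroup_size = 4,
                            min_support = 60,
                            consensus_threshold = 0.70,
                            pp_cutoff = 0.90,
                            max_iterations = 3,
                            min_model_span = 0.4,
                            n_bootstrap = 100,
                            compactness = 0.5,
                            degradation_ratio_threshold = 2.0,
                            activity_ratio_threshold = 0.5,
                            activity_min_span = 0.6,
                            seed = 1) {
  if (gather_threshold <= 0 || phylo_threshold <= 0 ||
      any(final_thresholds <= 0) || default_final_threshold <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  if (any(final_thresholds > gather_threshold) ||
      default_final_threshold > gather_threshold) {
    stop("final thresholds must be at least as strict as gathering",
         call. = FALSE)
  }
  structure(list(gather_threshold = gather_threshold,
                 phylo_threshold = phylo_threshold,
                 final_thresholds = final_thresholds,
                 default_final_threshold = default_final_threshold,
                 min_fragment_length = min_fragment_length,
                 min_subgroup_size = min_subgroup_size,
                 min_support = min_support,
                 consensus_threshold = consensus_threshold,
                 pp_cutoff = pp_cutoff,
                 max_iterations = max_iterations,
                 min_model_span = min_model_span,
                 n_bootstrap = n_bootstrap,
                 compactness = compactness,
                 degradation_ratio_threshold = degradation_ratio_threshold,
                 activity_ratio_threshold = activity_ratio_threshold,
                 activity_min_span = activity_min_span,
                 seed = seed),
            class = "pipeline_config")
}

final_threshold_for <- function(config, domain) {
  if (domain %in% names(config$final_thresholds)) {
    config$final_thresholds[[domain]]
  } else {
    config$default_final_threshold
  }
}

#' Call a domain hit active or degraded
#'
#' A hit is degraded when its bit-score density (bits per match state)
#' falls below `ratio_threshold` times the median density of the reference
#' hits for that domain, or when its model-span fraction is below
#' `min_span` (a partial, eroded domain).
#'
#' @param hit One hit-table row.
#' @param ref_densities Bit-score densities of reference hits for the
#'   domain (at least 4 recommended).
#' @param model_length Number of match states of the domain model.
#' @param ratio_threshold Density ratio cutoff.
#' @param min_span Minimum span fraction.
#' @return `"active"` or `"degraded"`.
#' @export
call_domain_activity <- function(hit, ref_densities, model_length,
                                 ratio_threshold = 0.5, min_span = 0.6) {
  if (!length(ref_densities)) stop("empty reference score distribution",
                                   call. = FALSE)
  if (length(ref_densities) < 4) {
    warning("fewer than 4 reference hits; activity call is unreliable",
            call. = FALSE)
  }
  density <- hit$bit_score / model_length
  if (hit$model_span_frac < min_span ||
      density < ratio_threshold * stats::median(ref_densities)) {
    "degraded"
  } else {
    "active"
  }
}

#' Assemble a protein's domain architecture and nomenclature
#'
#' Overlapping hits are resolved in favour of the lowest E-value (ties:
#' higher bit score, then lexicographic model name). The protein class is
#' `long` when both SYNTH and HD survive, `SAS` for SYNTH only, `SAH` for
#' HD only, `none` otherwise. The bracket nomenclature lists H/S in N-to-C
#' order, uppercase for active and lowercase for degraded domains, e.g.
#' `[HS]`, `[hS]`, `[S]`.
#'
#' @param hits Hit-table rows for one protein (domain-kind models).
#' @param activity Character vector (`"active"`/`"degraded"`) parallel to
#'   `hits` rows.
#' @return List with `domains` (data frame name/start/end/activity),
#'   `nomenclature`, `class`.
#' @export
assign_architecture <- function(hits, activity) {
  if (!nrow(hits)) {
    return(list(domains = data.frame(name = character(0),
                                     start = integer(0), end = integer(0),
                                     activity = character(0)),
                nomenclature = "[]", class = "none"))
  }
  ord <- order(hits$e_value, -hits$bit_score, hits$model, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  activity <- activity[ord]
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ov <- FALSE
    for (j in which(keep)) {
      if (hits$env_start[[i]] <= hits$env_end[[j]] &&
          hits$env_end[[i]] >= hits$env_start[[j]]) { ov <- TRUE; break }
    }
    keep[[i]] <- !ov
  }
  hits <- hits[keep, , drop = FALSE]
  activity <- activity[keep]
  pos <- order(hits$env_start)
  hits <- hits[pos, , drop = FALSE]
  activity <- activity[pos]
  has_synth <- "SYNTH" %in% hits$model
  has_hd <- "HD" %in% hits$model
  cls <- if (has_synth && has_hd) "long" else if (has_synth) "SAS" else
    if (has_hd) "SAH" else "none"
  letters_nc <- character(0)
  for (i in seq_len(nrow(hits))) {
    if (hits$model[[i]] == "HD") {
      letters_nc <- c(letters_nc,
                      if (activity[[i]] == "active") "H" else "h")
    } else if (hits$model[[i]] == "SYNTH") {
      letters_nc <- c(letters_nc,
                      if (activity[[i]] == "active") "S" else "s")
    }
  }
  list(domains = data.frame(name = hits$model, start = hits$env_start,
                            end = hits$env_end, activity = activity,
                            stringsAsFactors = FALSE),
       nomenclature = paste0("[", paste(letters_nc, collapse = ""), "]"),
       class = cls)
}

#' Parse a bracket nomenclature string
#'
#' Inverse of the nomenclature produced by [assign_architecture()].
#'
#' @param x String like `"[hS]"`.
#' @return Data frame with `domain` and `activity` in N-to-C order.
#' @export
parse_nomenclature <- function(x) {
  if (!grepl("^\\[[HhSs]*\\]$", x)) {
    stop(sprintf("malformed nomenclature '%s'", x), call. = FALSE)
  }
  chars <- strsplit(gsub("\\[|\\]", "", x), "")[[1]]
  data.frame(
    domain = ifelse(toupper(chars) == "H", "HD", "SYNTH"),
    activity = ifelse(chars %in% c("H", "S"), "active", "degraded"),
    stringsAsFactors = FALSE)
}

# profile-anchored alignment: one row per member sequence, one column per
# match state of the domain model (deletions -> gaps)
profile_anchor_alignment <- function(hmm, records) {
  rows <- character(0)
  for (r in seq_len(nrow(records))) {
    v <- viterbi(hmm, records$residues[[r]])
    chars <- rep("-", hmm$M)
    ok <- !is.na(v$match_map)
    chars[ok] <- strsplit(records$residues[[r]], "")[[1]][v$match_map[ok]]
    rows[[records$id[[r]]]] <- paste(chars, collapse = "")
  }
  alignment(rows)
}

# per-subgroup clade-level degradation flags: for each subgroup with at
# least min_subgroup_size members present in >= 2 domain frames, stack the
# frames and ask domain_divergence_ratio which domain diverges
# disproportionately within the clade; returns "SG domain" keys
clade_degraded_domains <- function(st, config) {
  flags <- character(0)
  labs <- st$labels[!is.na(st$labels)]
  for (sg in unique(labs)) {
    members <- names(labs)[labs == sg]
    use <- Filter(function(d) {
      sum(members %in% rownames(st$frames[[d]])) >= config$min_subgroup_size
    }, names(st$frames))
    if (length(use) < 2) next
    common <- members
    for (d in use) common <- intersect(common, rownames(st$frames[[d]]))
    if (length(common) < config$min_subgroup_size) next
    blocks <- lapply(use, function(d) {
      unclass(st$frames[[d]])[common, , drop = FALSE]
    })
    combined <- alignment(do.call(cbind, blocks))
    offsets <- c(0, cumsum(vapply(blocks, ncol, integer(1))))
    cols <- lapply(seq_along(use), function(i) {
      (offsets[[i]] + 1):offsets[[i + 1]]
    })
    names(cols) <- use
    ratios <- tryCatch(
      domain_divergence_ratio(combined, common, cols,
                              config$degradation_ratio_threshold),
      error = function(e) NULL)
    if (is.null(ratios)) next
    flags <- c(flags, paste(sg, ratios$domain[ratios$degraded_like]))
  }
  flags
}

# deterministic small seed derived from a master seed and a tag
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  (seed * 7919 + h) %% 2000000011
}

#' Iteratively classify proteomes into superfamily subgroups
#'
#' Per round: (1) build domain HMMs from the current member alignments
#' (the seed alignments in round 1); (2) scan all proteomes at the
#' gathering threshold; (3) drop fragments; (4) restrict to the phylogeny
#' E-value gate and align members in the profile frame, trimming gap-rich
#' columns; (5) build an NJ tree with bootstrap supports per domain and
#' extract well-supported subgroups; (6) build subgroup HMMs for
#' subgroups with enough taxa; (7) reassign every member to its best
#' subgroup model by E-value. Rounds repeat until the labels stabilise or
#' `max_iterations` is reached. A final pass applies the per-domain final
#' thresholds, calls domain activity and architectures, and bins members
#' that fall in no qualifying subgroup as `div<domain>`.
#'
#' Synthetase-carrying proteins are classified on the SYNTH-frame tree;
#' hydrolase-only proteins on the HD-frame tree.
#'
#' @param proteomes Named list of sequence-record frames (one per genome,
#'   `organism` filled with the genome id).
#' @param seed_alns Named list of seed alignments, at least one of which
#'   must be named `SYNTH` or `HD`.
#' @param config A [pipeline_config()].
#' @return List of class `rsh_classification`: `labels` (data frame
#'   seq_id, genome_id, subgroup, nomenclature, class), `hits` (final hit
#'   table), `all_hits` (gathering-stage hits), `subgroups` (member lists),
#'   `trees` (per-domain support trees), `member_alns` (profile-frame
#'   alignments), `audit` (per-iteration log), `genomes`, `config`.
#' @export
iterative_classify <- function(proteomes, seed_alns, config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!length(seed_alns)) stop("need at least one seed alignment",
                               call. = FALSE)
  all_records <- do.call(rbind, unname(proteomes))
  genomes <- names(proteomes)
  member_alns <- seed_alns
  labels_prev <- NULL
  audit <- list()
  classify_domains <- intersect(c("SYNTH", "HD"), names(seed_alns))
  if (!length(classify_domains)) {
    stop("seed alignments must include SYNTH or HD", call. = FALSE)
  }

  for (iter in seq_len(config$max_iterations)) {
    models <- lapply(names(member_alns), function(d) {
      hmm <- build_hmm(member_alns[[d]], name = d, kind = "domain")
      calibrate(hmm, seed = derive_seed(config$seed, paste0("cal_", d)))
    })
    names(models) <- names(member_alns)

    hits <- scan_proteome(models, all_records,
                          gather_threshold = config$gather_threshold,
                          min_model_span = config$min_model_span)
    if (iter == 1 && !nrow(hits)) {
      stop("no family members found", call. = FALSE)
    }
    long_records <- filter_fragments(all_records,
                                     config$min_fragment_length)
    hits <- hits[hits$seq_id %in% long_records$id, , drop = FALSE]

    # profile-anchored member alignments per domain; trees and subgroup
    # extraction only for the classification domains
    trees <- list(); frames <- list(); partitions <- list()
    for (d in names(models)) {
      dh <- hits[hits$model == d & hits$e_value <= config$phylo_threshold, ,
                 drop = FALSE]
      if (nrow(dh) < 4) next
      recs <- long_records[match(dh$seq_id, long_records$id), , drop = FALSE]
      aln <- profile_anchor_alignment(models[[d]], recs)
      aln <- trim_gappy_columns(aln)
      frames[[d]] <- aln
      if (!d %in% classify_domains) next
      tr <- bootstrap_supports(aln, n_replicates = config$n_bootstrap,
                               seed = derive_seed(config$seed,
                                                  paste0("boot_", d, iter)))
      trees[[d]] <- tr
      partitions[[d]] <- extract_subgroups(
        tr, min_support = config$min_support,
        min_size = config$min_subgroup_size,
        compactness = config$compactness,
        genomes = stats::setNames(long_records$organism, long_records$id))
    }
    if (!length(partitions)) stop("no family members found", call. = FALSE)

    synth_members <- if (!is.null(frames$SYNTH)) rownames(frames$SYNTH)
                     else character(0)
    # subgroup catalogue: SYNTH-frame subgroups cover synthetase carriers;
    # HD-frame subgroups only where mostly hydrolase-only proteins
    groups <- list()
    if (!is.null(partitions$SYNTH)) {
      for (nm in names(partitions$SYNTH$subgroups)) {
        groups[[length(groups) + 1]] <- list(
          domain = "SYNTH", members = partitions$SYNTH$subgroups[[nm]])
      }
    }
    if (!is.null(partitions$HD)) {
      for (nm in names(partitions$HD$subgroups)) {
        mem <- partitions$HD$subgroups[[nm]]
        if (mean(mem %in% synth_members) < 0.5) {
          groups[[length(groups) + 1]] <- list(domain = "HD", members = mem)
        }
      }
    }
    ord <- order(-vapply(groups, function(g) length(g$members), integer(1)),
                 vapply(groups, function(g) sort(g$members)[[1]],
                        character(1)), method = "radix")
    groups <- groups[ord]
    names(groups) <- if (length(groups)) paste0("SG", seq_along(groups))
                     else character(0)

    # subgroup HMMs in the domain frame, then best-model reassignment
    sub_models <- list()
    for (nm in names(groups)) {
      g <- groups[[nm]]
      rows <- intersect(g$members, rownames(frames[[g$domain]]))
      if (length(rows) < config$min_subgroup_size) next
      sub_aln <- alignment(unclass(frames[[g$domain]])[rows, , drop = FALSE])
      hmm <- build_hmm(sub_aln, name = nm, kind = "subgroup")
      hmm <- calibrate(hmm, seed = derive_seed(config$seed,
                                               paste0("cal_", nm)))
      sub_models[[nm]] <- hmm
    }

    labels <- stats::setNames(rep(NA_character_,
                                  length(unique(hits$seq_id))),
                              sort(unique(hits$seq_id), method = "radix"))
    for (sid in names(labels)) {
      dom <- if (sid %in% synth_members) "SYNTH"
             else if (!is.null(frames$HD) && sid %in% rownames(frames$HD))
               "HD" else NA_character_
      if (is.na(dom)) next
      cand <- Filter(function(m) groups[[m$name]]$domain == dom, sub_models)
      if (!length(cand)) next
      rec <- long_records[long_records$id == sid, , drop = FALSE]
      # log-scale E-values: linear-scale values underflow to 0 for strong
      # hits, which would make the best-model comparison a coin toss
      les <- vapply(cand, function(m) {
        v <- viterbi(m, rec$residues[[1]], traceback = FALSE)
        log_evalue(v$bit_score, m$calibration, max(nrow(long_records), 1))
      }, numeric(1))
      if (min(les) <= log(config$gather_threshold)) {
        labels[[sid]] <- names(cand)[[which.min(les)]]
      }
    }

    audit[[iter]] <- data.frame(
      iteration = iter, n_hits = nrow(hits),
      n_members = length(labels), n_subgroups = length(groups),
      n_assigned = sum(!is.na(labels)), stringsAsFactors = FALSE)

    stable <- !is.null(labels_prev) &&
      identical(labels_prev, labels)
    labels_prev <- labels

    # refresh member alignments for the next round's domain HMMs
    # (non-classification domains keep their seed alignments)
    member_alns[names(frames)] <- frames
    final_state <- list(models = models, sub_models = sub_models,
                        hits = hits, frames = frames, trees = trees,
                        groups = groups, labels = labels,
                        long_records = long_records)
    if (stable) break
  }

  st <- final_state
  # final pass: per-domain final thresholds, activity, architectures
  fin <- st$hits[st$hits$e_value <= vapply(st$hits$model,
                                           final_threshold_for,
                                           numeric(1), config = config), ,
                 drop = FALSE]
  ref_density <- lapply(split(fin, fin$model), function(df) {
    df$bit_score / vapply(df$model, function(m) st$models[[m]]$M,
                          numeric(1))
  })
  # clade-level degradation: a domain whose within-subgroup divergence is
  # disproportionate (ratio above threshold across >= 2 domain frames) is
  # degraded-like for every member of that subgroup, even where the
  # iteratively retrained HMM has accommodated the clade's sequences
  clade_degraded <- clade_degraded_domains(st, config)
  label_rows <- list()
  for (sid in sort(unique(fin$seq_id), method = "radix")) {
    ph <- fin[fin$seq_id == sid, , drop = FALSE]
    sg_of_sid <- st$labels[[sid]]
    act <- vapply(seq_len(nrow(ph)), function(i) {
      m <- ph$model[[i]]
      a <- call_domain_activity(ph[i, ], ref_density[[m]], st$models[[m]]$M,
                                ratio_threshold =
                                  config$activity_ratio_threshold,
                                min_span = config$activity_min_span)
      if (!is.null(sg_of_sid) && !is.na(sg_of_sid) &&
          paste(sg_of_sid, m) %in% clade_degraded) {
        a <- "degraded"
      }
      a
    }, character(1))
    arch <- assign_architecture(ph, act)
    if (arch$class == "none") next
    sg <- st$labels[[sid]]
    if (is.null(sg) || is.na(sg)) {
      sg <- paste0("div", if ("SYNTH" %in% ph$model) "SYNTH" else "HD")
    }
    label_rows[[length(label_rows) + 1]] <- data.frame(
      seq_id = sid, genome_id = ph$genome_id[[1]], subgroup = sg,
      nomenclature = arch$nomenclature, class = arch$class,
      stringsAsFactors = FALSE)
  }
  labels_df <- if (length(label_rows)) do.call(rbind, label_rows) else
    data.frame(seq_id = character(0), genome_id = character(0),
               subgroup = character(0), nomenclature = character(0),
               class = character(0), stringsAsFactors = FALSE)
  rownames(labels_df) <- NULL

  structure(list(labels = labels_df, hits = fin, all_hits = st$hits,
                 subgroups = lapply(st$groups, `[[`, "members"),
                 trees = st$trees, member_alns = st$frames,
                 audit = do.call(rbind, audit), genomes = genomes,
                 config = config),
            class = "rsh_classification")
}

#' @export
print.rsh_classification <- function(x, ...) {
  cat(sprintf("RSH classification: %d labelled proteins, %d subgroups, %d genomes\n",
              nrow(x$labels), length(x$subgroups), length(x$genomes)))
  invisible(x)
}

#' Genome complement table
#'
#' Per genome, the count of classified proteins per subgroup and the class
#' totals (long / SAS / SAH), ordered deterministically.
#'
#' @param classification An `rsh_classification` (or a list with `labels`
#'   and `genomes`).
#' @return Data frame with one row per genome: subgroup count columns
#'   (`n_<subgroup>`), then `long`, `SAS`, `SAH`.
#' @export
genome_complement <- function(classification) {
  labels <- classification$labels
  genomes <- classification$genomes %||% sort(unique(labels$genome_id),
                                              method = "radix")
  sgs <- sort(unique(labels$subgroup), method = "radix")
  out <- data.frame(genome_id = genomes, stringsAsFactors = FALSE)
  for (sg in sgs) {
    out[[paste0("n_", sg)]] <- vapply(genomes, function(g) {
      sum(labels$genome_id == g & labels$subgroup == sg)
    }, integer(1))
  }
  for (cl in c("long", "SAS", "SAH")) {
    out[[cl]] <- vapply(genomes, function(g) {
      sum(labels$genome_id == g & labels$class == cl)
    }, integer(1))
  }
  rownames(out) <- NULL
  out
}

#' Check genome complements against organisational rules
#'
#' Flags per genome: `SYNTH_WITHOUT_HYDROLASE` (an active synthetase with
#' no active hydrolase anywhere in the genome - a violation, never seen in
#' nature because unchecked alarmone synthesis is lethal),
#' `HYDROLASE_ONLY` (allowed, rare), `NO_RSH` (allowed), and `OK`
#' otherwise (at least one bifunctional or a balanced complement).
#'
#' @param classification An `rsh_classification`.
#' @return Data frame with `genome_id`, `flag`, `violation`.
#' @export
check_complement_rules <- function(classification) {
  labels <- classification$labels
  genomes <- classification$genomes %||% sort(unique(labels$genome_id),
                                              method = "radix")
  res <- lapply(genomes, function(g) {
    noms <- labels$nomenclature[labels$genome_id == g]
    active_s <- any(grepl("S", noms, fixed = TRUE))
    active_h <- any(grepl("H", noms, fixed = TRUE))
    if (!length(noms)) {
      flag <- "NO_RSH"; viol <- FALSE
    } else if (active_s && !active_h) {
      flag <- "SYNTH_WITHOUT_HYDROLASE"; viol <- TRUE
    } else if (active_h && !active_s) {
      flag <- "HYDROLASE_ONLY"; viol <- FALSE
    } else if (!active_s && !active_h) {
      flag <- "NO_RSH"; viol <- FALSE
    } else {
      flag <- "OK"; viol <- FALSE
    }
    data.frame(genome_id = g, flag = flag, violation = viol,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Serialize a classification result as deterministic JSON
#'
#' Rows are ordered deterministically, so two runs with the same inputs
#' and seed produce byte-identical files.
#'
#' @param classification An `rsh_classification`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classification_json <- function(classification, path) {
  labels <- classification$labels
  labels <- labels[order(labels$seq_id, method = "radix"), , drop = FALSE]
  rownames(labels) <- NULL
  hits <- classification$hits
  hits <- hits[order(hits$seq_id, hits$model, method = "radix"), ,
               drop = FALSE]
  rownames(hits) <- NULL
  comp <- genome_complement(classification)
  rules <- check_complement_rules(classification)
  obj <- list(labels = labels, hits = hits, complement = comp,
              rules = rules,
              subgroups = classification$subgroups,
              audit = classification$audit)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
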