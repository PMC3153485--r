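#' Remove gap-rich alignment columns
#'
#' Keeps columns whose gap fraction is strictly below `max_gap_frac` (so a
#' column that is exactly half gaps is removed at the default). The returned
#' alignment carries a `column_map` attribute giving, for each kept column,
#' its index in the input (composed with any existing map).
#'
#' @param aln Alignment matrix.
#' @param max_gap_frac Columns with gap fraction `>=` this are dropped.
#' @return Trimmed alignment with `column_map`.
#' @export
trim_gappy_columns <- function(aln, max_gap_frac = 0.5) {
  gap_frac <- colMeans(aln == "-")
  keep <- which(gap_frac < max_gap_frac)
  if (!length(keep)) stop("all columns exceed the gap-fraction limit",
                          call. = FALSE)
  prev <- attr(aln, "column_map")
  map <- if (is.null(prev)) keep else prev[keep]
  out <- aln[, keep, drop = FALSE]
  alignment(unclass(out), column_map = map)
}

#' Remove sequence fragments
#'
#' Drops records shorter than `min_length` residues (strictly: length 99 is
#' removed at the default, length 100 kept). Gap characters never occur in
#' sequence records so length is the residue count.
#'
#' @param records Sequence-record data frame.
#' @param min_length Minimum length kept.
#' @return Filtered records.
#' @export
filter_fragments <- function(records, min_length = 100) {
  records[nchar(records$residues) >= min_length, , drop = FALSE]
}

#' Collapse identical aligned rows
#'
#' Keeps the first occurrence of each distinct aligned string; consensus
#' computations assume this has been applied so that over-represented
#' identical sequences do not dominate.
#'
#' @param aln Alignment matrix.
#' @return Alignment with one representative per identical row.
#' @export
dedupe_identical <- function(aln) {
  rows <- alignment_strings(aln)
  keep <- !duplicated(unname(rows))
  alignment(unclass(aln)[keep, , drop = FALSE],
            column_map = attr(aln, "column_map"))
}

#' Consensus sequence at a percentage-similarity threshold
#'
#' Per column, among non-gap rows: a residue strictly exceeding `threshold`
#' support is reported uppercase; failing that, a physicochemical class
#' strictly exceeding `threshold` is reported as its lowercase
#' representative (first member); failing that, a column whose gap fraction
#' (over all rows) reaches `threshold` is reported `-`; anything else is
#' `x` (unconserved). Support comparisons are strict, so a 7-of-10 residue
#' does not clear the default 0.70 threshold while its fully-agreeing
#' physicochemical class does.
#'
#' @param aln Alignment matrix (deduplicate first; see [dedupe_identical()]).
#' @param threshold Similarity threshold in (0.5, 1].
#' @param classes Physicochemical partition, as [residue_classes()].
#' @param warn_duplicates Warn when identical rows are present.
#' @return Consensus string of length `ncol(aln)`.
#' @export
consensus <- function(aln, threshold = 0.70, classes = residue_classes(),
                      warn_duplicates = TRUE) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("consensus threshold must lie in (0.5, 1]", call. = FALSE)
  }
  if (warn_duplicates && anyDuplicated(unname(alignment_strings(aln)))) {
    warning("alignment contains identical rows; consensus assumes deduplication",
            call. = FALSE)
  }
  reps <- vapply(classes, `[[`, character(1), 1)
  cls_of <- residue_class_of(AA, classes)
  out <- vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    gaps <- col == "-"
    res <- col[!gaps & col != "X"]
    if (length(res)) {
      tab <- table(res) / length(res)
      if (max(tab) > threshold) return(names(tab)[which.max(tab)])
      cl <- residue_class_of(names(tab), classes)
      cl_support <- tapply(as.numeric(tab), cl, sum)
      if (length(cl_support) && max(cl_support) > threshold) {
        best <- names(cl_support)[which.max(cl_support)]
        return(tolower(reps[[best]]))
      }
    }
    if (mean(gaps) >= threshold) return("-")
    "x"
  }, character(1))
  paste(out, collapse = "")
}

# per-column consensus symbol + numeric support for one subgroup alignment;
# support is the residue (or class) fraction behind the symbol, 0 for x/-
consensus_profile <- function(aln, threshold = 0.70,
                              classes = residue_classes()) {
  symbols <- strsplit(consensus(aln, threshold, classes,
                                warn_duplicates = FALSE), "")[[1]]
  support <- vapply(seq_len(ncol(aln)), function(j) {
    col <- aln[, j]
    res <- col[col != "-" & col != "X"]
    if (!length(res)) return(0)
    s <- symbols[[j]]
    if (s == "x" || s == "-") return(0)
    if (s == toupper(s)) return(mean(res == s))
    cl <- residue_class_of(toupper(s), classes)
    mean(residue_class_of(res, classes) %in% cl)
  }, numeric(1))
  data.frame(column = seq_len(ncol(aln)), symbol = symbols,
             support = support,
             conserved = symbols != "x" & symbols != "-",
             stringsAsFactors = FALSE)
}

#' Classify a column's cross-subgroup conservation pattern
#'
#' Mirrors the conservation categories used when comparing subgroup
#' consensus alignments: `UNIVERSAL` (all subgroups conserved, compatible
#' symbols), `DISTINCTIVE_FOCAL` (the focal subgroup conserved where the
#' others either agree on something different or are unconserved),
#' `PAIR_NOT_FOCAL` / `PAIR_NOT_<name>` (all subgroups but one conserved and
#' agreeing), else `UNCONSERVED`. The result is invariant under permutation
#' of the non-focal subgroups.
#'
#' @param symbols Named character vector of per-subgroup consensus symbols
#'   for one column (as produced by [consensus()]).
#' @param conserved Named logical vector: is the subgroup's symbol a
#'   conserved residue/class call (support >= threshold)?
#' @param focal Name of the focal subgroup.
#' @param classes Physicochemical partition.
#' @return Category string.
#' @export
classify_column_conservation <- function(symbols, conserved, focal,
                                         classes = residue_classes()) {
  groups <- names(symbols)
  if (length(groups) < 2) stop("need at least 2 subgroup profiles",
                               call. = FALSE)
  if (!focal %in% groups) stop(sprintf("unknown focal subgroup '%s'", focal),
                               call. = FALSE)
  conserved <- conserved[groups]
  agree <- function(g) {
    all(vapply(g[-1], function(x) {
      symbols_compatible(symbols[[x]], symbols[[g[[1]]]], classes)
    }, logical(1)))
  }
  others <- setdiff(groups, focal)
  if (all(conserved) && agree(groups)) return("UNIVERSAL")
  if (conserved[[focal]]) {
    others_agree <- all(conserved[others]) && agree(others)
    if (others_agree && !symbols_compatible(symbols[[focal]],
                                            symbols[[others[[1]]]], classes)) {
      return("DISTINCTIVE_FOCAL")
    }
    if (!any(conserved[others])) return("DISTINCTIVE_FOCAL")
  }
  for (x in groups) {
    rest <- setdiff(groups, x)
    if (length(rest) >= 1 && all(conserved[rest]) && agree(rest) &&
        !(conserved[[x]] && agree(groups))) {
      if (conserved[[x]] && length(rest) == 1) next
      return(if (x == focal) "PAIR_NOT_FOCAL" else paste0("PAIR_NOT_", x))
    }
  }
  "UNCONSERVED"
}

#' Find columns conserved only in one group of sequences
#'
#' Returns alignment columns where the in-group reaches the similarity
#' threshold on one residue or physicochemical class while the out-group is
#' unconserved at the same threshold.
#'
#' @param aln Alignment matrix.
#' @param in_group,out_group Disjoint character vectors of row ids, each
#'   with at least 2 members.
#' @param threshold Similarity threshold.
#' @param classes Physicochemical partition.
#' @return Integer vector of column indices.
#' @export
find_group_specific_sites <- function(aln, in_group, out_group,
                                      threshold = 0.70,
                                      classes = residue_classes()) {
  if (length(intersect(in_group, out_group))) {
    stop("in_group and out_group overlap", call. = FALSE)
  }
  if (length(in_group) < 2 || length(out_group) < 2) {
    stop("each group needs at least 2 members", call. = FALSE)
  }
  missing <- setdiff(c(in_group, out_group), rownames(aln))
  if (length(missing)) stop(sprintf("unknown sequence id '%s'", missing[[1]]),
                            call. = FALSE)
  pin <- consensus_profile(aln[in_group, , drop = FALSE], threshold, classes)
  pout <- consensus_profile(aln[out_group, , drop = FALSE], threshold, classes)
  which(pin$conserved & !pout$conserved)
}
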