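#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet
#' @importFrom utils read.delim write.table
NULL

#' Construct a sequence-record collection
#'
#' Sequence collections are plain data frames with columns `id`, `organism`,
#' `residues` and `description`. Ids must be unique and non-empty; residues
#' are validated against the 20 canonical amino acids plus `X`.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of residue strings.
#' @param organism Optional organism / genome token per record.
#' @param description Optional free-text description per record.
#' @return A `data.frame` with one row per sequence.
#' @export
seq_records <- function(id, residues, organism = NA_character_,
                        description = "") {
  id <- as.character(id)
  if (any(!nzchar(id))) stop("sequence id must be non-empty", call. = FALSE)
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop(sprintf("duplicate sequence id: '%s'", dup[[1]]), call. = FALSE)
  }
  if (any(!nzchar(residues))) {
    stop(sprintf("empty residue string for id '%s'",
                 id[!nzchar(residues)][[1]]), call. = FALSE)
  }
  residues <- vapply(seq_along(residues), function(i) {
    clean_residues(residues[[i]], allow_gaps = FALSE, context = id[[i]])
  }, character(1))
  data.frame(id = id, organism = rep_len(as.character(organism), length(id)),
             residues = residues,
             description = rep_len(as.character(description), length(id)),
             stringsAsFactors = FALSE)
}

# locate the first line of `path` containing a character outside `legal_re`
first_bad_line <- function(path, legal_re) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">") || startsWith(ln, "#")) next
    if (grepl(legal_re, toupper(ln))) return(i)
  }
  NA_integer_
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A sequence-record data frame (see [seq_records()]); the FASTA
#'   header's first token becomes `id`, the remainder `description`. Order is
#'   preserved. Duplicate ids and illegal residue characters are errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (file.size(path) == 0) {
    return(seq_records(character(0), character(0)))
  }
  # Biostrings silently drops invalid one-letter codes, so scan the raw
  # lines first to report illegal characters with their line number
  bad_line <- first_bad_line(path, "[^ACDEFGHIKLMNPQRSTVWYXBZU \t]")
  if (!is.na(bad_line)) {
    stop(sprintf("illegal character in %s (line %d)", path, bad_line),
         call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) {
      bad <- first_bad_line(path, "[^ACDEFGHIKLMNPQRSTVWYXBZU \t]")
      stop(sprintf("malformed FASTA in %s%s: %s", path,
                   if (!is.na(bad)) sprintf(" (line %d)", bad) else "",
                   conditionMessage(e)), call. = FALSE)
    }
  )
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  resid <- as.character(set)
  legal_re <- paste0("[^", paste(AA, collapse = ""), "XBZU]")
  bad_rec <- which(grepl(legal_re, toupper(resid)))
  if (length(bad_rec)) {
    line <- first_bad_line(path, legal_re)
    stop(sprintf("illegal character in record '%s' (line %s of %s)",
                 ids[bad_rec[[1]]], line, path), call. = FALSE)
  }
  seq_records(ids, resid, description = desc)
}

#' Write sequence records to FASTA
#'
#' @param records Sequence-record data frame.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60) {
  set <- Biostrings::AAStringSet(records$residues)
  names(set) <- ifelse(nzchar(records$description),
                       paste(records$id, records$description),
                       records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct an alignment object
#'
#' Alignments are character matrices with one row per sequence (rownames are
#' ids) and one column per alignment position; gaps are `-`. An optional
#' `column_map` attribute maps current columns back to the columns of the
#' alignment they were derived from (strictly increasing).
#'
#' @param rows Named character vector of aligned strings, or a character
#'   matrix of single residues.
#' @param column_map Optional strictly increasing integer vector.
#' @return A character matrix of class `rsh_aln`.
#' @export
alignment <- function(rows, column_map = NULL) {
  if (is.matrix(rows)) {
    mat <- rows
  } else {
    if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
      stop("alignment rows must be named", call. = FALSE)
    }
    lens <- nchar(rows)
    if (length(unique(lens)) > 1) {
      off <- names(rows)[lens != lens[[1]]][[1]]
      stop(sprintf("ragged alignment: row '%s' has length %d, expected %d",
                   off, nchar(rows[[off]]), lens[[1]]), call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(toupper(rows), ""))
    rownames(mat) <- names(rows)
  }
  mat[mat == "."] <- "-"
  if (any(duplicated(rownames(mat)))) {
    stop(sprintf("duplicate sequence id: '%s'",
                 rownames(mat)[duplicated(rownames(mat))][[1]]), call. = FALSE)
  }
  all_gap <- apply(mat == "-", 1, all)
  if (any(all_gap)) {
    stop(sprintf("row '%s' contains no residues",
                 rownames(mat)[all_gap][[1]]), call. = FALSE)
  }
  if (!is.null(column_map)) {
    column_map <- as.integer(column_map)
    if (length(column_map) != ncol(mat) || any(diff(column_map) <= 0)) {
      stop("column_map must be strictly increasing with one entry per column",
           call. = FALSE)
    }
  }
  attr(mat, "column_map") <- column_map
  class(mat) <- c("rsh_aln", class(mat))
  mat
}

#' @export
print.rsh_aln <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d columns\n", nrow(x), ncol(x)))
  invisible(x)
}

# aligned strings (named character vector) from an alignment matrix
alignment_strings <- function(aln) {
  stats::setNames(apply(aln, 1, paste, collapse = ""), rownames(aln))
}

#' Read a multiple alignment
#'
#' Supports aligned FASTA (`afa`) and Stockholm (`stockholm`, read-only;
#' `#=GF`/`#=GC`/`#=GS`/`#=GR` annotation lines are ignored and wrapped
#' sequence blocks are concatenated). Gap characters `.` and `-` are both
#' normalised to `-`.
#'
#' @param path Input path.
#' @param format `"afa"` or `"stockholm"`.
#' @return An alignment matrix (see [alignment()]).
#' @export
read_alignment <- function(path, format = c("afa", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  if (format == "afa") {
    set <- Biostrings::readAAStringSet(path)
    rows <- stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*$", lines)]
    lines <- lines[!startsWith(lines, "#") & !startsWith(lines, "//")]
    parts <- strsplit(trimws(lines), "\\s+")
    bad <- which(lengths(parts) != 2)
    if (length(bad)) {
      stop(sprintf("malformed Stockholm sequence line: '%s'", lines[bad[[1]]]),
           call. = FALSE)
    }
    ids <- vapply(parts, `[[`, character(1), 1)
    seqs <- vapply(parts, `[[`, character(1), 2)
    rows <- vapply(split(seqs, factor(ids, levels = unique(ids))),
                   paste, character(1), collapse = "")
  }
  rows <- vapply(seq_along(rows), function(i) {
    clean_residues(chartr(".", "-", rows[[i]]), allow_gaps = TRUE,
                   context = names(rows)[[i]])
  }, character(1), USE.NAMES = FALSE) |> stats::setNames(names(rows))
  alignment(rows)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln Alignment matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  set <- Biostrings::AAStringSet(alignment_strings(aln))
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}

#' Read a Newick tree
#'
#' Internal node labels are interpreted as integer bootstrap supports
#' (0-100). Unbalanced parentheses are reported with their character
#' position.
#'
#' @param path Path to a Newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[[i]] == "(") depth <- depth + 1L
    if (chars[[i]] == ")") depth <- depth - 1L
    if (depth < 0L) {
      stop(sprintf("unbalanced ')' at position %d", i), call. = FALSE)
    }
  }
  if (depth > 0L) {
    stop(sprintf("unbalanced '(' (%d unclosed) in %s", depth, path),
         call. = FALSE)
  }
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop(sprintf("cannot parse Newick in %s", path),
                          call. = FALSE)
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are preserved to at least 6 decimals; integer node labels
#' (bootstrap supports) are written as internal node labels.
#'
#' @param tree An `ape::phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

HIT_COLUMNS <- c("seq_id", "genome_id", "model", "model_kind",
                 "env_start", "env_end", "bit_score", "e_value",
                 "model_span_frac")

#' Construct a domain-hit table
#'
#' One row per (sequence, model) domain hit. Coordinates are 1-based
#' inclusive envelope positions on the protein; `model_span_frac` is the
#' fraction of the profile's match states covered by the hit.
#'
#' @param seq_id,genome_id,model Character columns.
#' @param model_kind `"domain"` or `"subgroup"`.
#' @param env_start,env_end Integer envelope coordinates.
#' @param bit_score,e_value,model_span_frac Numeric columns.
#' @return A `data.frame` with the canonical column set.
#' @export
hit_table <- function(seq_id = character(0), genome_id = character(0),
                      model = character(0), model_kind = character(0),
                      env_start = integer(0), env_end = integer(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      model_span_frac = numeric(0)) {
  ht <- data.frame(seq_id = as.character(seq_id),
                   genome_id = as.character(genome_id),
                   model = as.character(model),
                   model_kind = as.character(model_kind),
                   env_start = as.integer(env_start),
                   env_end = as.integer(env_end),
                   bit_score = as.numeric(bit_score),
                   e_value = as.numeric(e_value),
                   model_span_frac = as.numeric(model_span_frac),
                   stringsAsFactors = FALSE)
  validate_hit_table(ht)
}

validate_hit_table <- function(ht) {
  if (nrow(ht)) {
    if (any(ht$env_start > ht$env_end)) {
      stop("hit with env_start > env_end", call. = FALSE)
    }
    if (any(ht$e_value < 0)) stop("negative E-value in hit table",
                                  call. = FALSE)
    if (any(ht$model_span_frac <= 0 | ht$model_span_frac > 1)) {
      stop("model_span_frac outside (0, 1]", call. = FALSE)
    }
    if (!all(ht$model_kind %in% c("domain", "subgroup"))) {
      stop("model_kind must be 'domain' or 'subgroup'", call. = FALSE)
    }
  }
  ht
}

#' Write / read a domain-hit table as TSV
#'
#' The TSV dialect has a fixed header
#' `seq_id genome_id model model_kind env_start env_end bit_score e_value
#' model_span_frac`; numeric columns are written with 17 significant digits
#' so the round trip is bit-exact.
#'
#' @param hits Hit table (see [hit_table()]).
#' @param path File path.
#' @return `write_hit_table`: `path` invisibly; `read_hit_table`: the table.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits[, HIT_COLUMNS, drop = FALSE]
  for (col in c("bit_score", "e_value", "model_span_frac")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hit_table
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character")
  missing <- setdiff(HIT_COLUMNS, names(df))
  if (length(missing)) {
    stop(sprintf("hit table missing column '%s'", missing[[1]]), call. = FALSE)
  }
  hit_table(seq_id = df$seq_id, genome_id = df$genome_id, model = df$model,
            model_kind = df$model_kind,
            env_start = as.integer(df$env_start),
            env_end = as.integer(df$env_end),
            bit_score = as.numeric(df$bit_score),
            e_value = as.numeric(df$e_value),
            model_span_frac = as.numeric(df$model_span_frac))
}
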