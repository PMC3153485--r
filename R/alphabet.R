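#' Amino-acid alphabet and physicochemical classes
#'
#' The package works over the 20 canonical amino acids plus `X` (unknown).
#' Ambiguity codes `B`, `Z` and `U` are mapped to `X` on input with a warning,
#' so downstream emission models see a fixed alphabet.
#'
#' @name alphabet
NULL

# canonical residue order used for all emission vectors / matrices
AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP_CHARS <- c("-", ".")

#' Default physicochemical residue classes
#'
#' A Dayhoff-like partition of the 20 residues used for "percentage
#' similarity" consensus calls and for deciding whether a fixed substitution
#' is radical (type II divergence): small/hydroxyl `AGST`, aliphatic `ILMV`,
#' aromatic `FYW`, basic `KRH`, acidic `DE`, amide `NQ`, and singletons `C`
#' and `P`. `X` belongs to no class.
#'
#' @return Named list of character vectors partitioning the 20 residues.
#' @export
#' @examples
#' residue_classes()$basic
residue_classes <- function() {
  list(
    small    = c("A", "G", "S", "T"),
    aliphatic = c("I", "L", "M", "V"),
    aromatic = c("F", "Y", "W"),
    basic    = c("K", "R", "H"),
    acidic   = c("D", "E"),
    amide    = c("N", "Q"),
    cysteine = "C",
    proline  = "P"
  )
}

# residue -> class name lookup (X and gaps map to NA)
residue_class_of <- function(residues, classes = residue_classes()) {
  map <- character(0)
  for (cl in names(classes)) map[classes[[cl]]] <- cl
  unname(map[toupper(residues)])
}

# TRUE when two consensus symbols denote the same conservation signal:
# identical letter (case-insensitive) or members of the same class.
symbols_compatible <- function(a, b, classes = residue_classes()) {
  if (is.na(a) || is.na(b)) return(FALSE)
  au <- toupper(a); bu <- toupper(b)
  if (au == bu) return(TRUE)
  ca <- residue_class_of(au, classes)
  cb <- residue_class_of(bu, classes)
  !is.na(ca) && !is.na(cb) && ca == cb
}

# validate a residue string; maps B/Z/U to X (warning), upper-cases.
# allow_gaps adds '-' to the legal set ('.' is normalised to '-' upstream).
clean_residues <- function(x, allow_gaps = FALSE, context = "sequence") {
  x <- toupper(x)
  if (grepl("[BZU]", x)) {
    warning(sprintf("%s: ambiguity codes B/Z/U mapped to X", context),
            call. = FALSE)
    x <- gsub("[BZU]", "X", x)
  }
  legal <- paste0("[^", paste(AA, collapse = ""), "X",
                  if (allow_gaps) "-" else "", "]")
  if (grepl(legal, x)) {
    bad <- regmatches(x, regexpr(legal, x))
    stop(sprintf("%s: illegal character '%s'", context, bad), call. = FALSE)
  }
  x
}
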