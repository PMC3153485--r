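#' Profile hidden Markov models
#'
#' A simplified local profile HMM in the Plan7 spirit: `M` match states with
#' position-specific emissions, interior insert states with a single shared
#' emission distribution, interior delete states, uniform local entry
#' (`B -> M_k` with probability `1/M`), and position-dependent exit
#' (`M_k -> E` with probability `1/(M - k + 1)`, so `M_M` always exits;
#' remaining transition mass is shared among `M/I/D` moves estimated from
#' the training alignment). Delete paths may run to `D_M`, which exits with
#' probability 1. Flanking residues outside the matched core are free:
#' scores are log2 odds of the core path versus the background, so a
#' sequence with no resemblance to the model scores at or below 0.
#'
#' There is no multi-hit mode and no claim of HMMER score compatibility.
#'
#' @name profilehmm
#' @useDynLib rshkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

LOG0 <- -Inf

lg2 <- function(p) ifelse(p > 0, log2(p), LOG0)

# exit probability from match state k in a model of M match states
exit_prob <- function(M) 1 / (M - seq_len(M) + 1)

#' Build a profile HMM from a multiple alignment
#'
#' Columns with gap fraction strictly below `max_gap_frac` become match
#' states (mirroring trimming to columns with <50% gaps); the rest are
#' insert columns. Match emissions are `(count + w * background)`
#' normalised, with `w = pseudocount_weight`; transition probabilities are
#' estimated from the observed match/insert/delete paths of the rows with
#' the same smoothing toward a uniform prior.
#'
#' @param aln Alignment matrix.
#' @param name Model name.
#' @param pseudocount_weight Total pseudocount mass added per distribution.
#' @param max_gap_frac Match-state gap-fraction rule.
#' @param background Length-20 background distribution (default uniform).
#' @param kind `"domain"` or `"subgroup"` (bookkeeping for hit tables).
#' @return A `profile_hmm` object.
#' @export
build_hmm <- function(aln, name = "model", pseudocount_weight = 1.0,
                      max_gap_frac = 0.5, background = rep(1 / 20, 20),
                      kind = "domain") {
  stopifnot(nrow(aln) >= 1)
  background <- background / sum(background)
  gap_frac <- colMeans(aln == "-")
  match_cols <- which(gap_frac < max_gap_frac)
  M <- length(match_cols)
  if (M == 0) stop("no alignment column qualifies as a match state",
                   call. = FALSE)
  w <- pseudocount_weight

  mat <- matrix(0, M, 20, dimnames = list(NULL, AA))
  for (j in seq_len(M)) {
    col <- aln[, match_cols[[j]]]
    obs <- col[col %in% AA]
    cnt <- table(factor(obs, levels = AA))
    mat[j, ] <- (as.numeric(cnt) + w * background) /
      (length(obs) + w)
  }

  # observed state paths: match column + residue -> M, + gap -> D;
  # insert column + residue -> I attached to the preceding match index
  is_match <- logical(ncol(aln))
  is_match[match_cols] <- TRUE
  midx <- cumsum(is_match)          # match index at/before each column
  cmm <- cmi <- cmd <- numeric(max(M - 1, 0))
  cim <- cii <- numeric(max(M - 1, 0))
  cdm <- cdd <- numeric(max(M - 1, 0))
  for (r in seq_len(nrow(aln))) {
    row <- aln[r, ]
    states <- character(0); pos <- integer(0)
    for (jc in seq_len(ncol(aln))) {
      res <- row[[jc]] != "-"
      if (is_match[[jc]]) {
        states <- c(states, if (res) "M" else "D"); pos <- c(pos, midx[[jc]])
      } else if (res && midx[[jc]] >= 1 && midx[[jc]] < M) {
        states <- c(states, "I"); pos <- c(pos, midx[[jc]])
      }
    }
    if (length(states) < 2) next
    for (t in seq_len(length(states) - 1)) {
      from <- states[[t]]; to <- states[[t + 1]]; k <- pos[[t]]
      if (k < 1 || k > M - 1) next
      if (from == "M") {
        if (to == "M" || (to == "D" && pos[[t + 1]] == k + 1)) {
          if (to == "M") cmm[k] <- cmm[k] + 1 else cmd[k] <- cmd[k] + 1
        } else if (to == "I") cmi[k] <- cmi[k] + 1
      } else if (from == "I") {
        if (to == "I") cii[k] <- cii[k] + 1 else if (to == "M")
          cim[k] <- cim[k] + 1
      } else if (from == "D") {
        if (to == "D") cdd[k] <- cdd[k] + 1 else if (to == "M")
          cdm[k] <- cdm[k] + 1
      }
    }
  }
  # unobserved bundles fall back to the uniform prior even at weight 0
  norm3 <- function(a, b, c) {
    tot <- a + b + c + w
    zero <- tot == 0
    list(ifelse(zero, 1 / 3, (a + w / 3) / tot),
         ifelse(zero, 1 / 3, (b + w / 3) / tot),
         ifelse(zero, 1 / 3, (c + w / 3) / tot))
  }
  norm2 <- function(a, b) {
    tot <- a + b + w
    zero <- tot == 0
    list(ifelse(zero, 1 / 2, (a + w / 2) / tot),
         ifelse(zero, 1 / 2, (b + w / 2) / tot))
  }
  tm <- norm3(cmm, cmi, cmd)
  ti <- norm2(cim, cii)
  td <- norm2(cdm, cdd)

  hmm <- structure(list(
    name = name, kind = kind, M = M,
    match_emissions = mat,
    insert_emissions = background,
    background = background,
    t_mm = tm[[1]], t_mi = tm[[2]], t_md = tm[[3]],
    t_im = ti[[1]], t_ii = ti[[2]],
    t_dm = td[[1]], t_dd = td[[2]],
    match_columns = match_cols,
    calibration = NULL
  ), class = "profile_hmm")
  validate_hmm(hmm)
}

validate_hmm <- function(hmm, tol = 1e-9) {
  stopifnot(hmm$M >= 1)
  if (any(abs(rowSums(hmm$match_emissions) - 1) > tol)) {
    stop("match emission rows must sum to 1", call. = FALSE)
  }
  if (abs(sum(hmm$insert_emissions) - 1) > tol ||
      abs(sum(hmm$background) - 1) > tol) {
    stop("emission distributions must sum to 1", call. = FALSE)
  }
  if (hmm$M > 1) {
    s3 <- hmm$t_mm + hmm$t_mi + hmm$t_md
    if (any(abs(s3 - 1) > tol) ||
        any(abs(hmm$t_im + hmm$t_ii - 1) > tol) ||
        any(abs(hmm$t_dm + hmm$t_dd - 1) > tol)) {
      stop("transition bundles must sum to 1", call. = FALSE)
    }
  }
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile HMM '%s' (%s): %d match states%s\n", x$name, x$kind,
              x$M, if (is.null(x$calibration)) "" else ", calibrated"))
  invisible(x)
}

#' Consensus (argmax-emission) sequence of a profile HMM
#'
#' @param hmm A `profile_hmm`.
#' @return Residue string of length `M`.
#' @export
hmm_consensus <- function(hmm) {
  paste(AA[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

# residue string -> integer indices into AA (X and anything unknown -> 21)
encode_residues <- function(seq) {
  idx <- match(strsplit(toupper(seq), "")[[1]], AA)
  idx[is.na(idx)] <- 21L
  idx
}

# per-call DP setup shared by viterbi and forward: emission log-odds and
# transition log-probabilities with exit mass folded in
dp_setup <- function(hmm, seq) {
  x <- encode_residues(seq)
  L <- length(x)
  M <- hmm$M
  lodds <- cbind(log2(sweep(hmm$match_emissions, 2, hmm$background, "/")), 0)
  E <- lodds[, x, drop = FALSE]              # M x L
  if (M == 1) dim(E) <- c(1L, L)
  iodds <- c(log2(hmm$insert_emissions / hmm$background), 0)
  q <- exit_prob(M)
  list(
    x = x, L = L, M = M, E = E, iem = iodds[x],
    lentry = -log2(M), lexit = lg2(q),
    lmm = lg2((1 - q[-M]) * hmm$t_mm), lmi = lg2((1 - q[-M]) * hmm$t_mi),
    lmd = lg2((1 - q[-M]) * hmm$t_md),
    lim = lg2(hmm$t_im), lii = lg2(hmm$t_ii),
    ldm = lg2(hmm$t_dm), ldd = lg2(hmm$t_dd)
  )
}

#' Viterbi local alignment of a sequence to a profile HMM
#'
#' @param hmm A `profile_hmm`.
#' @param seq Residue string.
#' @param traceback Recover the state path and envelope (default `TRUE`).
#' @return List with `bit_score` (log2 odds of the best core path versus
#'   background), and when `traceback` is `TRUE`: `state_path` (data frame
#'   of state/model position/sequence position), `env_start`/`env_end`
#'   (1-based inclusive envelope on the sequence), `k_start`/`k_end` (match
#'   states spanned), and `match_map` (per match state, the sequence
#'   position aligned to it, `NA` for deletions/outside).
#' @export
viterbi <- function(hmm, seq, traceback = TRUE) {
  d <- dp_setup(hmm, seq)
  M <- d$M; L <- d$L
  if (L == 0) stop("sequence must be non-empty", call. = FALSE)
  core <- .viterbi_core(d$E, d$iem, d$lentry, d$lexit, d$lmm, d$lmi,
                        d$lmd, d$lim, d$lii, d$ldm, d$ldd, traceback)
  out <- list(bit_score = core$bit_score)
  if (!traceback) return(out)
  if (!is.finite(core$bit_score)) {
    out$state_path <- data.frame(state = character(0), k = integer(0),
                                 i = integer(0))
    out$env_start <- NA_integer_; out$env_end <- NA_integer_
    out$k_start <- NA_integer_; out$k_end <- NA_integer_
    out$match_map <- rep(NA_integer_, M)
    return(out)
  }
  PM <- core$PM; PI <- core$PI; PD <- core$PD
  # walk the silent delete chain downwards at fixed residue count i,
  # starting from D_kk; returns the match state the chain came from
  walk_d <- function(kk, i) {
    repeat {
      path[[length(path) + 1]] <<- c("D", kk, i)
      if (PD[[kk, i]] == 1L) return(kk - 1L)
      kk <- kk - 1L
    }
  }
  path <- list()
  i <- core$best_i; k <- core$best_k
  k_end <- core$best_k
  if (core$best_state == 1L) k <- walk_d(M, i)  # path ended in D_M
  repeat {
    path[[length(path) + 1]] <- c("M", k, i)
    ptr <- PM[[k, i]]
    if (ptr == 1L) { env_start <- i; break }
    if (ptr == 2L) { i <- i - 1L; k <- k - 1L }
    else if (ptr == 3L) {
      # from I_{k-1}: consume inserted residues backwards
      kI <- k - 1L; i <- i - 1L
      repeat {
        path[[length(path) + 1]] <- c("I", kI, i)
        pI <- PI[[kI, i]]
        i <- i - 1L
        if (pI == 1L) { k <- kI; break }
      }
    } else {
      i <- i - 1L
      k <- walk_d(k - 1L, i)
    }
  }
  path <- rev(path)
  sp <- data.frame(state = vapply(path, `[[`, character(1), 1),
                   k = as.integer(vapply(path, `[[`, character(1), 2)),
                   i = as.integer(vapply(path, `[[`, character(1), 3)),
                   stringsAsFactors = FALSE)
  mm <- rep(NA_integer_, M)
  mrows <- sp$state == "M"
  mm[sp$k[mrows]] <- sp$i[mrows]
  out$state_path <- sp
  out$env_start <- env_start
  out$env_end <- core$best_i
  out$k_start <- sp$k[[1]]
  out$k_end <- k_end
  out$match_map <- mm
  out
}

#' Forward score of a sequence under a profile HMM
#'
#' Log2 of the summed odds over all legal local core paths; always at least
#' the Viterbi score for the same input.
#'
#' @inheritParams viterbi
#' @return Bit score (numeric scalar).
#' @export
forward <- function(hmm, seq) {
  d <- dp_setup(hmm, seq)
  if (d$L == 0) stop("sequence must be non-empty", call. = FALSE)
  .forward_core(d$E, d$iem, d$lentry, d$lexit, d$lmm, d$lmi, d$lmd,
                d$lim, d$lii, d$ldm, d$ldd)
}

#' Fit a Gumbel distribution to scores by maximum likelihood
#'
#' @param scores Numeric vector of (Viterbi) bit scores.
#' @return List with `lambda` (1/scale, > 0) and `mu` (location).
#' @export
fit_gumbel <- function(scores) {
  if (length(scores) < 10) stop("need at least 10 scores", call. = FALSE)
  if (stats::sd(scores) < 1e-12) {
    stop("degenerate scores: all values (nearly) equal", call. = FALSE)
  }
  beta0 <- stats::sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(par) {
    mu <- par[[1]]; beta <- exp(par[[2]])
    z <- (scores - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "BFGS")
  list(lambda = 1 / exp(fit$par[[2]]), mu = fit$par[[1]])
}

#' Calibrate a profile HMM for E-values
#'
#' Scores `n_samples` i.i.d. background sequences of length `sample_length`
#' with [viterbi()] and fits a Gumbel to the scores by maximum likelihood.
#' Deterministic for a given seed.
#'
#' @param hmm A `profile_hmm`.
#' @param n_samples Number of background sequences.
#' @param sample_length Length of each.
#' @param seed Integer seed.
#' @return The model with a `calibration` list (`lambda`, `mu`,
#'   `n_samples`, `sample_length`, `seed`) attached.
#' @export
calibrate <- function(hmm, n_samples = 200, sample_length = 250, seed = 1) {
  scores <- with_local_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      seq <- paste(sample(AA, sample_length, replace = TRUE,
                          prob = hmm$background), collapse = "")
      viterbi(hmm, seq, traceback = FALSE)$bit_score
    }, numeric(1))
  })
  fit <- fit_gumbel(scores)
  hmm$calibration <- list(lambda = fit$lambda, mu = fit$mu,
                          n_samples = n_samples,
                          sample_length = sample_length, seed = seed)
  hmm
}

#' E-value of a bit score under a Gumbel calibration
#'
#' `E = N * (1 - exp(-exp(-lambda * (S - mu))))`, strictly decreasing in the
#' score `S`.
#'
#' @param bit_score Numeric score(s).
#' @param calibration Calibration list with `lambda`, `mu`.
#' @param database_size Number of sequences searched (`N >= 1`).
#' @return E-value(s).
#' @export
evalue <- function(bit_score, calibration, database_size = 1) {
  if (is.null(calibration)) stop("model is not calibrated", call. = FALSE)
  stopifnot(database_size >= 1)
  database_size *
    (1 - exp(-exp(-calibration$lambda * (bit_score - calibration$mu))))
}

# natural-log E-value, stable for scores where the E-value underflows:
# with u = exp(-lambda (S - mu)), E = N (1 - exp(-u)) and log E =
# log N + log(-expm1(-u)), falling back to log u for tiny u
log_evalue <- function(bit_score, calibration, database_size = 1) {
  lu <- -calibration$lambda * (bit_score - calibration$mu)
  u <- exp(lu)
  log(database_size) +
    ifelse(u < 1e-12, lu, log(-expm1(-pmax(u, 1e-300))))
}

#' Scan a proteome with a set of calibrated profile HMMs
#'
#' One hit is reported per (sequence, model) pair whose E-value passes the
#' gathering threshold and whose aligned match-state span covers at least
#' `min_model_span` of the model.
#'
#' @param models List of calibrated `profile_hmm` objects.
#' @param records Sequence-record data frame (the `organism` column is used
#'   as `genome_id`).
#' @param gather_threshold Permissive E-value gate.
#' @param min_model_span Minimum fraction of match states covered.
#' @param database_size Effective database size for E-values; defaults to
#'   the number of records scanned.
#' @return A hit table (see [hit_table()]).
#' @export
scan_proteome <- function(models, records, gather_threshold = 1e-2,
                          min_model_span = 0.4, database_size = NULL) {
  if (is.null(database_size)) database_size <- max(nrow(records), 1)
  rows <- list()
  for (m in models) {
    if (is.null(m$calibration)) {
      stop(sprintf("model '%s' is not calibrated", m$name), call. = FALSE)
    }
    for (r in seq_len(nrow(records))) {
      v <- viterbi(m, records$residues[[r]])
      if (!is.finite(v$bit_score)) next
      e <- evalue(v$bit_score, m$calibration, database_size)
      span <- (v$k_end - v$k_start + 1) / m$M
      if (e <= gather_threshold && span >= min_model_span) {
        rows[[length(rows) + 1]] <- data.frame(
          seq_id = records$id[[r]], genome_id = records$organism[[r]],
          model = m$name, model_kind = m$kind,
          env_start = v$env_start, env_end = v$env_end,
          bit_score = v$bit_score, e_value = e,
          model_span_frac = span, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(hit_table())
  validate_hit_table(do.call(rbind, rows))
}

#' Serialize / deserialize a profile HMM as JSON
#'
#' @param hmm A `profile_hmm`.
#' @param path File path.
#' @return `write_hmm_json`: `path` invisibly; `read_hmm_json`: the model.
#' @export
write_hmm_json <- function(hmm, path) {
  obj <- unclass(hmm)
  obj$match_emissions <- unname(as.data.frame(obj$match_emissions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mat <- as.matrix(obj$match_emissions)
  dimnames(mat) <- list(NULL, AA)
  hmm <- structure(list(
    name = obj$name, kind = obj$kind, M = as.integer(obj$M),
    match_emissions = mat,
    insert_emissions = as.numeric(obj$insert_emissions),
    background = as.numeric(obj$background),
    t_mm = as.numeric(obj$t_mm), t_mi = as.numeric(obj$t_mi),
    t_md = as.numeric(obj$t_md),
    t_im = as.numeric(obj$t_im), t_ii = as.numeric(obj$t_ii),
    t_dm = as.numeric(obj$t_dm), t_dd = as.numeric(obj$t_dd),
    match_columns = as.integer(obj$match_columns),
    calibration = if (is.null(obj$calibration)) NULL else obj$calibration
  ), class = "profile_hmm")
  validate_hmm(hmm)
}

# run code under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
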