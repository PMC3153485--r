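test_that("model building follows the gap rule and pseudocount formula", {
  aln <- alignment(c(r1 = "ACD", r2 = "ACD", r3 = "ACD", r4 = "ACD"))
  hmm <- build_hmm(aln)
  expect_equal(hmm$M, 3)
  expect_equal(names(which.max(hmm$match_emissions[1, ])), "A")

  gappy <- alignment(c(r1 = "A-CD", r2 = "A-CD", r3 = "AECD", r4 = "A-CD"))
  hmm2 <- build_hmm(gappy)
  expect_equal(hmm2$M, 3)                          # 0.75 gaps >= 0.5: dropped
  expect_identical(hmm2$match_columns, c(1L, 3L, 4L))

  half <- alignment(c(r1 = "A-D", r2 = "AED"))     # col 2: 0.5 gaps, dropped
  expect_equal(build_hmm(half)$M, 2)

  two <- alignment(c(r1 = "A", r2 = "A"))
  hmm3 <- build_hmm(two, pseudocount_weight = 1)
  expect_equal(unname(hmm3$match_emissions[1, "A"]), (2 + 0.05) / 3)

  allgap <- alignment(c(r1 = "A--", r2 = "-C-", r3 = "--D", r4 = "A--"))
  expect_error(build_hmm(allgap), "match state")
})

test_that("probability bundles are normalized after build and round trip", {
  for (s in 1:5) {
    aln <- random_alignment(8, 40, seed = 200 + s, gap_frac = 0.15)
    hmm <- build_hmm(aln, name = paste0("m", s))
    expect_true(all(abs(rowSums(hmm$match_emissions) - 1) < 1e-9))
    expect_true(all(abs(hmm$t_mm + hmm$t_mi + hmm$t_md - 1) < 1e-9))
    f <- withr::local_tempfile(fileext = ".json")
    write_hmm_json(hmm, f)
    back <- read_hmm_json(f)
    expect_true(all(abs(rowSums(back$match_emissions) - 1) < 1e-9))
    seq <- paste(sample(AA20, 30, replace = TRUE), collapse = "")
    expect_equal(viterbi(back, seq, traceback = FALSE)$bit_score,
                 viterbi(hmm, seq, traceback = FALSE)$bit_score)
  }
})

test_that("Viterbi and forward agree with exhaustive path enumeration", {
  for (M in 1:4) {
    for (L in 1:5) {
      for (rep in 1:2) {
        hmm <- random_toy_hmm(M, seed = M * 100 + L * 10 + rep)
        set.seed(M * 1000 + L * 10 + rep)
        seq <- paste(sample(c("A", "C", "D", "E"), L, replace = TRUE),
                     collapse = "")
        oracle <- brute_hmm_scores(hmm, seq)
        v <- viterbi(hmm, seq)
        expect_equal(v$bit_score, oracle$viterbi, tolerance = 1e-9)
        expect_equal(forward(hmm, seq), oracle$forward, tolerance = 1e-9)
      }
    }
  }
})

test_that("Viterbi ranks true signal above shuffles and respects dominance", {
  aln <- random_alignment(12, 60, seed = 31)
  hmm <- build_hmm(aln, name = "sig")
  cons <- hmm_consensus(hmm)
  for (s in 1:20) {
    set.seed(400 + s)
    shuf <- paste(sample(strsplit(cons, "")[[1]]), collapse = "")
    expect_gte(viterbi(hmm, cons, traceback = FALSE)$bit_score,
               viterbi(hmm, shuf, traceback = FALSE)$bit_score)
  }
  # forward sums over paths, so it dominates the single best path
  for (s in 1:100) {
    hmm_s <- random_toy_hmm(sample(2:4, 1), seed = 500 + s)
    set.seed(600 + s)
    seq <- paste(sample(AA20, sample(3:8, 1), replace = TRUE),
                 collapse = "")
    expect_gte(forward(hmm_s, seq) + 1e-9,
               viterbi(hmm_s, seq, traceback = FALSE)$bit_score)
  }
})

test_that("a sequence the model cannot emit scores at or below zero", {
  aln <- alignment(c(r1 = "AAAA", r2 = "AAAA", r3 = "AAAA"))
  hmm <- build_hmm(aln, pseudocount_weight = 0)
  expect_lte(viterbi(hmm, "CCCC", traceback = FALSE)$bit_score, 0)
})

test_that("Gumbel calibration is deterministic and recovers parameters", {
  aln <- random_alignment(10, 30, seed = 77)
  hmm <- build_hmm(aln)
  c1 <- calibrate(hmm, n_samples = 50, sample_length = 60, seed = 3)
  c2 <- calibrate(hmm, n_samples = 50, sample_length = 60, seed = 3)
  expect_identical(c1$calibration, c2$calibration)
  expect_gt(c1$calibration$lambda, 0)

  expect_error(fit_gumbel(rep(5, 100)), "degenerate")

  # direct draws at known parameters: inverse-CDF sampling
  set.seed(42)
  lambda <- 0.67; mu <- 5.0
  x <- mu - log(-log(runif(5000))) / lambda
  fit <- fit_gumbel(x)
  expect_equal(fit$lambda, lambda, tolerance = 0.05)
  expect_equal(fit$mu, mu, tolerance = 0.05 * mu)
})

test_that("E-values follow the Gumbel closed form and the staged gates", {
  cal <- list(lambda = 0.7, mu = 10)
  expect_equal(evalue(10, cal, 1), 1 - exp(-1), tolerance = 1e-12)
  es <- evalue(seq(5, 60, by = 0.5), cal, 100)
  expect_true(all(diff(es) < 0))

  # a hit at E = 1e-3 passes gathering (1e-2) but fails the final
  # synthetase gate (1e-4)
  e <- 1e-3
  cfg <- pipeline_config()
  expect_true(e <= cfg$gather_threshold)
  expect_false(e <= cfg$final_thresholds[["SYNTH"]])
})

test_that("proteome scanning hits consensus sequences and not decoys", {
  seeds <- ref_seed_alns()
  models <- lapply(names(seeds), function(d) {
    calibrate(build_hmm(seeds[[d]], name = d),
              seed = rshkit:::derive_seed(1, paste0("cal_", d)))
  })
  names(models) <- names(seeds)

  expect_equal(nrow(scan_proteome(models, seq_records(character(0),
                                                      character(0)))), 0)

  cons <- seq_records(paste0("cons_", names(models)),
                      vapply(models, hmm_consensus, character(1)),
                      organism = "gX")
  hits <- scan_proteome(models, cons)
  for (d in names(models)) {
    own <- hits[hits$seq_id == paste0("cons_", d) & hits$model == d, ]
    expect_equal(nrow(own), 1)
    expect_lte(own$e_value, 1e-2)
  }

  # decoy-only proteomes: nothing survives the final thresholds
  cfg <- pipeline_config()
  n_final_hits <- 0
  for (s in 1:10) {
    set.seed(700 + s)
    decoys <- seq_records(
      sprintf("d%02d_%d", 1:20, s),
      vapply(1:20, function(i) {
        paste(sample(AA20, sample(150:400, 1), replace = TRUE),
              collapse = "")
      }, character(1)), organism = "gD")
    hits_d <- scan_proteome(models[c("SYNTH", "HD")], decoys)
    if (nrow(hits_d)) {
      keep <- hits_d$e_value <= vapply(hits_d$model, function(m) {
        cfg$final_thresholds[[m]]
      }, numeric(1))
      n_final_hits <- n_final_hits + sum(keep)
    }
  }
  expect_equal(n_final_hits, 0)

  uncal <- build_hmm(seeds$SYNTH, name = "raw")
  expect_error(scan_proteome(list(uncal), cons), "not calibrated")
})
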