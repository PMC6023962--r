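# Generation model: scenario algebra, Pgen evaluation (brute force vs the
# forward dynamic program), and EM inference.

# Independent brute-force oracle: realize every (delV, delJ, insertion
# string) tuple by direct string assembly and compare with the read.
oracle_scenarios <- function(seq, germline, d_max, i_max) {
  hits <- 0L
  combos <- list()
  ins_strings <- ""
  for (k in seq_len(i_max)) {
    grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), k))
    ins_strings <- c(ins_strings, apply(grid, 1, paste0, collapse = ""))
  }
  for (vi in seq_len(nrow(germline$v))) for (ji in seq_len(nrow(germline$j))) {
    vseq <- germline$v$seq[vi]; jseq <- germline$j$seq[ji]
    mdv <- min(d_max, nchar(vseq) - germline$v$anchor[vi] - 3)
    mdj <- min(d_max, germline$j$anchor[ji])
    for (dv in 0:mdv) for (dj in 0:mdj) for (ins in ins_strings) {
      made <- paste0(substr(vseq, 1, nchar(vseq) - dv), ins,
                     substr(jseq, dj + 1, nchar(jseq)))
      if (made == seq) {
        hits <- hits + 1L
        combos[[hits]] <- list(vi = vi, ji = ji, dv = dv, dj = dj, ins = ins)
      }
    }
  }
  list(n = hits, combos = combos)
}

# Independent probability of a scenario straight from the tables.
oracle_prob <- function(cmb, params) {
  ins <- cmb$ins
  p_nt <- 1
  if (nchar(ins) > 0) {
    b <- strsplit(ins, "")[[1]]
    p_nt <- params$ins_init[b[1]]
    if (length(b) > 1)
      for (t in 2:length(b)) p_nt <- p_nt * params$ins_trans[b[t - 1], b[t]]
  }
  params$p_vj[cmb$vi, cmb$ji] * params$p_delv[cmb$vi, cmb$dv + 1] *
    params$p_delj[cmb$ji, cmb$dj + 1] * params$p_ins[nchar(ins) + 1] * p_nt
}

test_that("realize_scenario concatenates trimmed V, insert and trimmed J", {
  g <- toy_germline()
  v <- g$v[1, ]; j <- g$j[1, ]
  sc <- list(v_name = v$name, j_name = j$name, del_v = 0L, del_j = 0L,
             ins_seq = "")
  expect_equal(realize_scenario(sc, g), paste0(v$seq, j$seq))
  sc2 <- list(v_name = v$name, j_name = j$name, del_v = 1L, del_j = 2L,
              ins_seq = "GG")
  expect_equal(realize_scenario(sc2, g),
               paste0(substr(v$seq, 1, nchar(v$seq) - 1), "GG",
                      substr(j$seq, 3, nchar(j$seq))))
  # deletions may not cross the conserved anchors
  bad_v <- list(v_name = v$name, j_name = j$name,
                del_v = nchar(v$seq) - v$anchor - 2, del_j = 0L, ins_seq = "")
  expect_error(realize_scenario(bad_v, g), "anchor")
  bad_j <- list(v_name = v$name, j_name = j$name, del_v = 0L,
                del_j = j$anchor + 1, ins_seq = "")
  expect_error(realize_scenario(bad_j, g), "anchor")
})

test_that("enumerate_scenarios agrees with an exhaustive string oracle", {
  g <- toy_germline()
  p <- toy_params()
  set.seed(31)
  pool <- simulate_pool(12, shrink_params(p, 2, 2), g, frame = "any", seed = 31)
  for (i in seq_len(nrow(pool))) {
    sc <- enumerate_scenarios(pool$seq[i], g, d_max = 2, i_max = 2)
    orc <- oracle_scenarios(pool$seq[i], g, d_max = 2, i_max = 2)
    expect_equal(nrow(sc), orc$n)
    expect_true(all(sc$del_v <= 2 & sc$del_j <= 2 & nchar(sc$ins_seq) <= 2))
    # every enumerated scenario realizes the read
    for (r in seq_len(nrow(sc))) {
      expect_equal(realize_scenario(sc[r, ], g), pool$seq[i])
    }
  }
  # too-short read: no scenario
  expect_equal(nrow(enumerate_scenarios("ACGT", g, 2, 2)), 0)
})

test_that("pgen_brute matches an independent tuple-loop computation", {
  g <- toy_germline()
  p <- shrink_params(toy_params(), 2, 2)
  set.seed(17)
  pool <- simulate_pool(10, p, g, frame = "any", seed = 17)
  for (i in seq_len(nrow(pool))) {
    res <- pgen_brute(pool$seq[i], p, g)
    orc <- oracle_scenarios(pool$seq[i], g, p$d_max, p$i_max)
    expect_equal(res$n_scenarios, orc$n)
    expect_equal(res$pgen,
                 sum(vapply(orc$combos, oracle_prob, numeric(1), params = p)),
                 tolerance = 1e-12)
    expect_equal(res$pgen, exp(res$log_pgen))
  }
})

test_that("degenerate models give exact Pgen values", {
  g <- tiny_germline()
  p <- init_generation_params(g, d_max = 0, i_max = 0)
  read <- paste0(g$v$seq, g$j$seq)
  expect_equal(pgen_brute(read, p, g)$pgen, 1.0)
  expect_equal(pgen_forward(read, p, g)$pgen, 1.0)
  # a read inconsistent with every V prefix has Pgen 0
  bad <- paste0("TTTT", substr(read, 5, nchar(read)))
  expect_equal(pgen_forward(bad, p, g)$pgen, 0)
  expect_equal(pgen_forward(bad, p, g)$log_pgen, -Inf)
})

test_that("forward DP reproduces brute-force Pgen within 1e-10 relative", {
  g <- toy_germline()
  p <- shrink_params(toy_params(), 2, 2)
  pool <- simulate_pool(25, p, g, frame = "any", seed = 57)
  pb <- vapply(pool$seq, function(s) pgen_brute(s, p, g)$pgen, numeric(1))
  pf <- vapply(pool$seq, function(s) pgen_forward(s, p, g)$pgen, numeric(1))
  expect_true(all(abs(pb - pf) / pmax(pb, 1e-300) < 1e-10))
})

test_that("Pgen sums to one over the generable support of a tiny model", {
  g <- tiny_germline()
  p <- shrink_params(toy_generation_params(tiny_germline()), 1, 1)
  sc <- expand.grid(del_v = 0:1, del_j = 0:1,
                    ins_seq = c("", "A", "C", "G", "T"),
                    stringsAsFactors = FALSE)
  sc$v_name <- g$v$name; sc$j_name <- g$j$name
  seqs <- unique(vapply(seq_len(nrow(sc)),
                        function(i) realize_scenario(sc[i, ], g), character(1)))
  tot <- sum(vapply(seqs, function(s) pgen_forward(s, p, g)$pgen, numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-9)
})

test_that("EM on one unambiguous read concentrates all probability on it", {
  g <- toy_germline()
  read <- paste0(g$v$seq[2], "AA", substr(g$j$seq[3], 2, nchar(g$j$seq[3])))
  fit <- suppressMessages(
    fit_generation_model(read, g, d_max = 2, i_max = 2,
                         frame_correction = FALSE, max_iter = 50))
  expect_equal(unname(fit$params$p_vj[2, 3]), 1, tolerance = 1e-9)
  expect_equal(unname(fit$params$p_delv[2, 1]), 1, tolerance = 1e-9)  # delV = 0
  expect_equal(unname(fit$params$p_delj[3, 2]), 1, tolerance = 1e-9)  # delJ = 1
  expect_equal(unname(fit$params$p_ins["2"]), 1, tolerance = 1e-9)
})

test_that("EM log-likelihood trace is monotone and recovery improves with n", {
  g <- toy_germline()
  p <- toy_params()
  of_small <- simulate_pool(2000, p, g, frame = "out_of_frame", seed = 301)
  fit <- fit_generation_model(of_small, g, d_max = 6, i_max = 10,
                              tol = 1e-6, max_iter = 200)
  expect_true(all(diff(fit$logLik_trace) > -1e-9))
  expect_true(all(abs(rowSums(fit$params$p_delv) - 1) < 1e-9))
  tv_small <- total_variation(fit$params$p_vj, p$p_vj)
  of_big <- simulate_pool(20000, p, g, frame = "out_of_frame", seed = 302)
  fit_big <- fit_generation_model(of_big, g, d_max = 6, i_max = 10,
                                  tol = 1e-6, max_iter = 200)
  tv_big <- total_variation(fit_big$params$p_vj, p$p_vj)
  expect_lt(tv_big, tv_small + 0.005)
  # one extra EM pass at the fixed point moves parameters by less than tol
  refit <- fit_generation_model(of_big, g, d_max = 6, i_max = 10,
                                init = fit_big$params, tol = 1e-6, max_iter = 2)
  expect_lt(max(abs(refit$params$p_vj - fit_big$params$p_vj)), 1e-3)
})

test_that("reads with no consistent scenario are excluded, all-excluded errors", {
  g <- toy_germline()
  junk <- strrep("ACGT", 20)
  expect_error(suppressMessages(fit_generation_model(junk, g, d_max = 2, i_max = 2)),
               "no read")
  p <- toy_params()
  pool <- simulate_pool(50, p, g, frame = "out_of_frame", seed = 5)
  expect_message(
    fit_generation_model(c(pool$seq, junk), g, d_max = 6, i_max = 10,
                         max_iter = 3),
    "excluded 1/51")
})

test_that("pre-selection sampling is reproducible and matches gene usage", {
  g <- toy_germline()
  p <- toy_params()
  a <- sample_pre_repertoire(p, g, n = 2000, seed = 9)
  b <- sample_pre_repertoire(p, g, n = 2000, seed = 9)
  expect_identical(a, b)
  expect_true(all(nchar(a$cdr3_aa) == a$L))
  expect_true(all(nchar(a$cdr3_nt) == 3 * a$L))
  # productive-only filter leaves no stops
  expect_false(any(grepl("*", a$cdr3_aa, fixed = TRUE)))
  big <- sample_pre_repertoire(p, g, n = 50000, seed = 10)
  # V usage within 3 binomial SDs of the (frame-conditioned) truth; the
  # productive filter reweights genes only mildly, so allow the bound around
  # a large-sample reference instead of the raw p_vj marginal
  ref <- sample_pre_repertoire(p, g, n = 50000, seed = 11)
  for (v in rownames(p$p_vj)) {
    ph <- mean(big$v_name == v)
    pr <- mean(ref$v_name == v)
    se <- sqrt(pr * (1 - pr) * 2 / 50000)
    expect_lt(abs(ph - pr), 4 * se + 1e-6)
  }
})

test_that("generation model serializes to JSON and back", {
  g <- toy_germline()
  p <- toy_params()
  path <- tempfile(fileext = ".json")
  write_generation_model(p, path)
  back <- read_generation_model(path)
  expect_equal(back$p_vj, p$p_vj)
  expect_equal(back$p_delv, p$p_delv)
  expect_equal(back$p_ins, p$p_ins)
  expect_equal(back$ins_trans, p$ins_trans)
})
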