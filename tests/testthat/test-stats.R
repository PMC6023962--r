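# Repertoire statistics: CDR3 extraction, molecular mass, relative
# differences, and the significance tests against independent oracles.

test_that("extract_cdr3 classifies frames and translates between anchors", {
  g <- toy_germline()
  # build reads with controlled junction length: span = 18 - delV - delJ + ins
  mk <- function(ins) {
    sc <- list(v_name = g$v$name[1], j_name = g$j$name[2], del_v = 0L,
               del_j = 0L, ins_seq = ins)
    realize_scenario(sc, g)
  }
  reads <- data.frame(id = c("inframe", "shift1", "shift2"),
                      seq = c(mk("AAA"), mk("A"), mk("AA")),
                      stringsAsFactors = FALSE)
  a <- assign_vj(reads, g)
  cdr3 <- extract_cdr3(reads, a, g)
  expect_equal(cdr3$frame_class[1], "in_frame_productive")
  expect_true(all(cdr3$frame_class[2:3] == "out_of_frame"))
  expect_equal(cdr3$length_aa[1], 7)           # span 21 nt
  expect_equal(nchar(cdr3$aa_seq[1]), 7)
  expect_equal(substr(cdr3$aa_seq[1], 1, 1), "C")
  expect_equal(substr(cdr3$aa_seq[1], 7, 7), "F")
  # a read with an in-frame stop inside the CDR3 is classed "stop"
  stop_read <- data.frame(id = "s", seq = mk("TAA"), stringsAsFactors = FALSE)
  sa <- assign_vj(stop_read, g)
  expect_equal(extract_cdr3(stop_read, sa, g)$frame_class, "stop")
})

test_that("molecular_mass matches an independent reference implementation", {
  # free glycine and additivity
  expect_equal(suppressWarnings(molecular_mass("")), 18.02, tolerance = 0.01)
  expect_equal(molecular_mass("G"), 75.07, tolerance = 0.01)
  expect_equal(molecular_mass("GG") - molecular_mass("G"), 57.05,
               tolerance = 0.01)
  expect_error(molecular_mass("GXZ"), "unknown")
  expect_warning(molecular_mass(""), "degenerate")
  # cross-check against seqinr's protein molecular weight
  set.seed(12)
  aas <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  peps <- vapply(1:20, function(i)
    paste(sample(aas, sample(3:15, 1), replace = TRUE), collapse = ""),
    character(1))
  ref <- vapply(peps, function(s) seqinr::pmw(strsplit(s, "")[[1]]), numeric(1))
  expect_equal(molecular_mass(peps), round(unname(ref), 2), tolerance = 0.02)
  # ceiling mode rounds up
  expect_gte(molecular_mass("WKY", mode = "ceiling"), molecular_mass("WKY"))
})

test_that("relative-difference measures behave as ratio minus one", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rel_diff_sd(x, x), 0)
  expect_equal(rel_diff_sd(c(1, 3), c(1, 5)), sd(c(1, 3)) / sd(c(1, 5)) - 1)
  # if sd = 1 against of sd = 2 gives -0.5
  expect_equal(rel_diff_sd(c(0, 1) * sqrt(2), c(0, 2) * sqrt(2)), -0.5)
  expect_equal(rel_diff_mean(2 * x, x), 1)
  expect_error(rel_diff_sd(x, rep(1, 5)), "zero standard deviation")
  expect_error(rel_diff_sd(1, x), "n >= 2")
  # scale invariance of the SD relative difference
  y <- c(2, 2, 3, 7, 9)
  expect_equal(rel_diff_sd(3.7 * x, 3.7 * y), rel_diff_sd(x, y))
})

test_that("F and t tests match their closed forms", {
  set.seed(5)
  x <- rnorm(40, sd = 2); y <- rnorm(55, sd = 1.3)
  ft <- variance_f_test(x, y)
  expect_equal(ft$statistic, var(x) / var(y), tolerance = 1e-12)
  fval <- var(x) / var(y)
  p_manual <- 2 * min(pf(fval, 39, 54), 1 - pf(fval, 39, 54))
  expect_equal(ft$p.value, p_manual, tolerance = 1e-10)
  # x = y gives F = 1 and (equal df) p = 1
  ft1 <- variance_f_test(x, x)
  expect_equal(ft1$statistic, 1)
  expect_equal(ft1$p.value, 1)
  expect_error(variance_f_test(rep(1, 5), y), "degenerate")

  tt <- mean_t_test(x, y)
  se <- sqrt(var(x) / 40 + var(y) / 55)
  tstat <- (mean(x) - mean(y)) / se
  df <- se^4 / ((var(x) / 40)^2 / 39 + (var(y) / 55)^2 / 54)
  expect_equal(tt$statistic, tstat, tolerance = 1e-10)
  expect_equal(tt$p.value, 2 * pt(-abs(tstat), df), tolerance = 1e-10)
})

test_that("test p-values are calibrated and powered on simulated samples", {
  set.seed(99)
  reps <- 400
  p_null <- replicate(reps, {
    variance_f_test(rnorm(30), rnorm(30))$p.value
  })
  ks <- suppressWarnings(stats::ks.test(p_null, "punif"))
  expect_gt(ks$p.value, 1e-3)
  p_alt <- replicate(50, variance_f_test(rnorm(500, sd = 1),
                                         rnorm(500, sd = 2))$p.value)
  expect_true(all(p_alt < 0.001))
})

test_that("pq_spearman equals rank-then-Pearson and hits the extremes", {
  expect_equal(pq_spearman(c(1, 2, 3, 4), c(0.1, 0.2, 0.3, 0.4)), 1)
  expect_equal(pq_spearman(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  set.seed(8)
  p <- exp(rnorm(30)); q <- exp(rnorm(30))
  q[5] <- q[7]          # a tie
  manual <- cor(rank(log(p)), rank(log(q)))
  expect_equal(pq_spearman(p, q), manual, tolerance = 1e-12)
  expect_error(pq_spearman(c(1, 2), c(1, 2)), "3")
})

test_that("wilcoxon_by_aa matches a brute-force signed-rank computation", {
  res <- wilcoxon_by_aa(rep("G", 5), c(0.2, 0.1, 0.5, 0.3, 0.4))
  expect_equal(res$V, 15)  # all positive: V = n(n+1)/2
  res0 <- wilcoxon_by_aa(rep("P", 5), -c(0.2, 0.1, 0.5, 0.3, 0.4))
  expect_equal(res0$V, 0)
  set.seed(21)
  x <- rnorm(12)
  ranks <- rank(abs(x))
  v_manual <- sum(ranks[x > 0])
  res2 <- wilcoxon_by_aa(rep("C", 12), x)
  expect_equal(res2$V, v_manual)
  expect_equal(res2$p,
               stats::wilcox.test(x, mu = 0, exact = TRUE)$p.value)
  # zeros are dropped; all-zero groups reported as NA
  resz <- wilcoxon_by_aa(rep("A", 6), rep(0, 6))
  expect_true(is.na(resz$V))
  mix <- wilcoxon_by_aa(c(rep("G", 6), rep("P", 6)),
                        c(1, 2, 3, 4, 5, 6, -1, -2, -3, 4, 5, 0))
  expect_equal(nrow(mix), 2)
  expect_equal(mix$n[mix$aa == "P"], 5)
})

test_that("codon_aa_variance separates within- from between-amino-acid spread", {
  codons <- names(igkselect:::.GENETIC_CODE)
  tab <- matrix(NA_real_, 64, 3, dimnames = list(codons, 1:3))
  aa <- igkselect:::.GENETIC_CODE
  # all synonymous codons equal within each amino acid: var_within = 0
  for (a in unique(aa[aa != "*"])) tab[aa == a, ] <- which(unique(aa) == a)
  cv <- codon_aa_variance(tab)
  expect_equal(cv$var_within, 0)
  expect_gt(cv$var_between, 0)
  # all equal: both zero
  tab2 <- tab; tab2[] <- 1.5; tab2[aa == "*", ] <- NA
  cv2 <- codon_aa_variance(tab2)
  expect_equal(cv2$var_within, 0)
  expect_equal(cv2$var_between, 0)
})

test_that("stats_report contrasts selected against unselected CDR3 records", {
  set.seed(4)
  mkrec <- function(L) data.frame(length_aa = L, mass = 110 * L + rnorm(length(L), 0, 20))
  rep_ <- stats_report(mkrec(round(rnorm(400, 7, 0.8))),
                       mkrec(round(rnorm(400, 7, 1.6))))
  expect_lt(rep_$sd_rel_diff_length, 0)
  expect_lt(rep_$f_test_length$p.value, 0.01)
  expect_output(print(rep_), "CDR3 length")
})
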