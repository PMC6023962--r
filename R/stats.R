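# Summary statistics contrasting in-frame (selected) and out-of-frame
# (unselected) repertoires: CDR3 length and molecular-mass distributions,
# their relative-difference measures, significance tests, p-q correlations
# and the codon/amino-acid variance decomposition of log selection factors.

#' Extract the CDR3 record of assigned reads
#'
#' The CDR3 runs from the conserved V-gene cysteine codon through the
#' conserved J-gene anchor codon inclusive. Reads whose junction shifts this
#' span out of frame are classed `out_of_frame`; in-frame reads containing a
#' stop codon downstream of the V anchor are classed `stop`; the rest are
#' `in_frame_productive`. For non-productive reads the translation covers
#' the complete codons of the span (stops appear as `*`) and the mass sums
#' the non-stop residues.
#'
#' @param reads Data frame with `id`, `seq`.
#' @param assignments Output of [assign_vj()] for the same reads.
#' @param germline A `germline_set`.
#' @return Data frame with `read_id`, `v_name`, `j_name`, `cdr3_nt`,
#'   `aa_seq`, `length_aa`, `mass`, `frame_class`, `usable` (FALSE when an
#'   anchor was trimmed away).
#' @export
extract_cdr3 <- function(reads, assignments, germline) {
  a <- assignments
  seqs <- reads$seq[match(a$read_id, reads$id)]
  ns <- nchar(seqs)
  vi <- match(a$v_name, germline$v$name)
  ji <- match(a$j_name, germline$j$name)
  av <- germline$v$anchor[vi]
  aj <- germline$j$anchor[ji]
  lj <- nchar(germline$j$seq)[ji]
  del_j <- lj - (ns - a$j_start)
  usable <- a$assigned & !is.na(vi) & (a$v_end >= av + 3) & (del_j <= aj) &
    (del_j >= 0)
  span <- ifelse(usable, a$j_start - av + (aj - del_j) + 3L, NA_integer_)
  cdr3_nt <- ifelse(usable, substring(seqs, av + 1, av + span), NA_character_)
  frame_class <- rep(NA_character_, nrow(a))
  aa_seq <- rep(NA_character_, nrow(a))
  k <- which(usable)
  if (length(k) > 0) {
    of <- span[k] %% 3L != 0L
    frame_class[k[of]] <- "out_of_frame"
    aa_seq[k] <- translate_nt(substring(cdr3_nt[k], 1, span[k] %/% 3L * 3L))
    inf <- k[!of]
    if (length(inf) > 0) {
      tail_len <- (ns[inf] - av[inf]) %/% 3L * 3L
      full <- translate_nt(substring(seqs[inf], av[inf] + 1, av[inf] + tail_len))
      frame_class[inf] <- ifelse(has_stop(full), "stop", "in_frame_productive")
    }
  }
  mass <- rep(NA_real_, nrow(a))
  ok <- !is.na(aa_seq) & nchar(gsub("*", "", aa_seq, fixed = TRUE)) > 0
  mass[ok] <- molecular_mass(gsub("*", "", aa_seq[ok], fixed = TRUE))
  data.frame(read_id = a$read_id, v_name = a$v_name, j_name = a$j_name,
             cdr3_nt = cdr3_nt, aa_seq = aa_seq,
             length_aa = ifelse(usable, span %/% 3L, NA_integer_),
             mass = mass, frame_class = frame_class, usable = usable,
             stringsAsFactors = FALSE)
}

#' Molecular mass of peptide sequences
#'
#' Average (not monoisotopic) residue masses plus one water, rounded to two
#' decimals. `mode = "ceiling"` rounds up instead.
#'
#' @param aa_seq Character vector of amino-acid strings (standard 20 letters).
#' @param mode `"round"` (half-even, default) or `"ceiling"`.
#' @return Numeric vector of masses in Daltons.
#' @export
molecular_mass <- function(aa_seq, mode = c("round", "ceiling")) {
  mode <- match.arg(mode)
  out <- vapply(aa_seq, function(s) {
    if (nchar(s) == 0) {
      warnf("empty peptide: returning the mass of water (degenerate)")
      return(.WATER_MASS)
    }
    res <- .RESIDUE_MASS[strsplit(s, "")[[1]]]
    if (anyNA(res)) stopf("unknown amino-acid letter in '%s'", s)
    sum(res) + .WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
  if (mode == "round") round(out, 2) else ceiling(out * 100) / 100
}

#' Relative difference of standard deviations (selected vs unselected)
#'
#' `sd(if_values)/sd(of_values) - 1`, so 0 encodes no selection and negative
#' values a narrower post-selection distribution.
#'
#' @param if_values,of_values Numeric samples (each of size >= 2).
#' @return A single number.
#' @export
rel_diff_sd <- function(if_values, of_values) {
  if (length(if_values) < 2 || length(of_values) < 2) stopf("need n >= 2")
  s0 <- stats::sd(of_values)
  if (s0 == 0) stopf("unselected sample has zero standard deviation")
  stats::sd(if_values) / s0 - 1
}

#' @rdname rel_diff_sd
#' @export
rel_diff_mean <- function(if_values, of_values) {
  if (length(if_values) < 2 || length(of_values) < 2) stopf("need n >= 2")
  m0 <- mean(of_values)
  if (m0 == 0) stopf("unselected sample has zero mean")
  mean(if_values) / m0 - 1
}

#' Two-sided F test of equal variances
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` (variance ratio) and `p.value`.
#' @export
variance_f_test <- function(x, y) {
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("degenerate variance in F test")
  ft <- stats::var.test(x, y)
  list(statistic = unname(ft$statistic), p.value = ft$p.value)
}

#' Welch two-sided t test of equal means
#'
#' @param x,y Numeric samples.
#' @return List with `statistic` and `p.value`.
#' @export
mean_t_test <- function(x, y) {
  tt <- stats::t.test(x, y)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Spearman correlation between log generation probability and log selection
#'
#' @param gen_probs Positive generation probabilities.
#' @param sel_factors Positive selection factors, paired with `gen_probs`.
#' @return Spearman's rho (average ranks for ties).
#' @export
pq_spearman <- function(gen_probs, sel_factors) {
  if (length(gen_probs) != length(sel_factors)) stopf("length mismatch")
  keep <- is.finite(gen_probs) & is.finite(sel_factors) &
    gen_probs > 0 & sel_factors > 0
  if (sum(keep) < 3) stopf("need at least 3 positive pairs")
  stats::cor(log(gen_probs[keep]), log(sel_factors[keep]), method = "spearman")
}

#' One-sample Wilcoxon signed-rank tests of log selection factors by amino acid
#'
#' Tests, per amino acid, whether its log selection factors (across CDR3
#' positions/lengths) are centred on zero. Zero values are dropped
#' (signed-rank convention); the exact null distribution is used for n <= 25
#' and the continuity-corrected normal approximation above.
#'
#' @param aa Character vector of amino-acid labels.
#' @param log_q Numeric vector of log selection factors, paired with `aa`.
#' @param min_n Minimum group size after dropping zeros (default 5).
#' @return Data frame with `aa`, `n`, `V` (sum of positive ranks) and `p`
#'   (`NA` when a group is all zeros or too small).
#' @export
wilcoxon_by_aa <- function(aa, log_q, min_n = 5) {
  stopifnot(length(aa) == length(log_q))
  keep <- !is.na(log_q)
  res <- lapply(sort(unique(aa[keep])), function(a) {
    x <- log_q[keep & aa == a]
    x <- x[x != 0]
    if (length(x) < min_n)
      return(data.frame(aa = a, n = length(x), V = NA_real_, p = NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(x, mu = 0,
                                              exact = length(x) <= 25,
                                              correct = TRUE))
    data.frame(aa = a, n = length(x), V = unname(wt$statistic), p = wt$p.value)
  })
  do.call(rbind, res)
}

#' Codon versus amino-acid variance of log selection factors
#'
#' Decomposes length-averaged codon-level log selection factors into the
#' pooled variance of codons around the mean of their (position, amino acid)
#' group and the variance of those group means. Amino acids with a single
#' defined codon contribute only to the between component.
#'
#' @param model A `selection_model` with codon factors, or a codon x position
#'   matrix of log factors as returned by `average_log_q(model, "codon")$codon`.
#' @return List with `var_within`, `var_between` and their `ratio`.
#' @export
codon_aa_variance <- function(model) {
  tab <- if (inherits(model, "selection_model")) {
    if (is.null(model$q_codon)) stopf("model has no codon-level factors")
    average_log_q(model, "codon")$codon
  } else model
  aa <- .GENETIC_CODE[rownames(tab)]
  long <- data.frame(aa = rep(aa, ncol(tab)),
                     pos = rep(seq_len(ncol(tab)), each = nrow(tab)),
                     lq = as.vector(tab))
  long <- long[!is.na(long$lq) & long$aa != "*", , drop = FALSE]
  grp <- interaction(long$aa, long$pos, drop = TRUE)
  mns <- tapply(long$lq, grp, mean)
  dev <- long$lq - mns[grp]
  ngrp <- nlevels(grp)
  var_within <- if (nrow(long) > ngrp)
    sum(dev^2) / (nrow(long) - ngrp) else 0
  var_between <- stats::var(as.vector(mns))
  list(var_within = var_within, var_between = var_between,
       ratio = var_within / var_between)
}

#' Repertoire-level statistics report
#'
#' Contrasts the CDR3 length and mass of a selected (in-frame) set against
#' an unselected (out-of-frame or model-generated) set: relative differences
#' of SDs and means, the F test on variances and the Welch t test on means.
#'
#' @param if_cdr3 CDR3 records of the selected set ([extract_cdr3()] rows or
#'   any data frame with `length_aa` and `mass`).
#' @param of_cdr3 CDR3 records of the unselected set.
#' @return List of class `repertoire_stats` with the relative differences
#'   and test results for both length and mass.
#' @export
stats_report <- function(if_cdr3, of_cdr3) {
  pick <- function(x, col) {
    v <- x[[col]]
    v[!is.na(v)]
  }
  li <- pick(if_cdr3, "length_aa"); lo <- pick(of_cdr3, "length_aa")
  mi <- pick(if_cdr3, "mass"); mo <- pick(of_cdr3, "mass")
  out <- list(
    n_if = length(li), n_of = length(lo),
    sd_rel_diff_length = rel_diff_sd(li, lo),
    sd_rel_diff_mass = rel_diff_sd(mi, mo),
    mean_rel_diff_length = rel_diff_mean(li, lo),
    mean_rel_diff_mass = rel_diff_mean(mi, mo),
    f_test_length = variance_f_test(li, lo),
    f_test_mass = variance_f_test(mi, mo),
    t_test_length = mean_t_test(li, lo),
    t_test_mass = mean_t_test(mi, mo))
  class(out) <- "repertoire_stats"
  out
}

#' @export
print.repertoire_stats <- function(x, ...) {
  cat(sprintf("Repertoire contrast (n_if = %d, n_of = %d)\n", x$n_if, x$n_of))
  cat(sprintf("  CDR3 length: SD rel diff %+.4f (F p = %.3g), mean rel diff %+.4f (t p = %.3g)\n",
              x$sd_rel_diff_length, x$f_test_length$p.value,
              x$mean_rel_diff_length, x$t_test_length$p.value))
  cat(sprintf("  CDR3 mass:   SD rel diff %+.4f (F p = %.3g), mean rel diff %+.4f (t p = %.3g)\n",
              x$sd_rel_diff_mass, x$f_test_mass$p.value,
              x$mean_rel_diff_mass, x$t_test_mass$p.value))
  invisible(x)
}
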