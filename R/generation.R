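# The VJ-recombination ("generation") model:
#   P(scenario) = P(V,J) P(delV | V) P(delJ | J) P(insL) P(inserted bases),
# with inserted bases drawn from a first-order Markov chain. Deletions are
# counted on the 3' end of V and the 5' end of J; scenarios that would remove
# a conserved anchor codon have probability zero (anchor protection).

#' Construct a generation-parameter object
#'
#' @param p_vj Joint probability matrix over (V gene, J gene), with row and
#'   column names matching the germline set.
#' @param p_delv Matrix of per-V deletion-count distributions (columns are
#'   0..`d_max` deletions).
#' @param p_delj Matrix of per-J deletion-count distributions.
#' @param p_ins Probability vector over insertion lengths 0..`i_max`.
#' @param ins_init Initial distribution of the inserted-nucleotide Markov
#'   chain over A, C, G, T.
#' @param ins_trans 4x4 transition matrix of the inserted-nucleotide chain
#'   (rows = current base, columns = next base).
#' @return An object of class `generation_params`.
#' @export
generation_params <- function(p_vj, p_delv, p_delj, p_ins, ins_init, ins_trans) {
  out <- list(p_vj = p_vj, p_delv = p_delv, p_delj = p_delj, p_ins = p_ins,
              ins_init = ins_init, ins_trans = ins_trans,
              d_max = ncol(p_delv) - 1L, i_max = length(p_ins) - 1L)
  class(out) <- "generation_params"
  validate_generation_params(out)
  out
}

#' Validate generation parameters
#'
#' Checks non-negativity and that every distribution sums to one.
#' @param params A `generation_params` object.
#' @param tol Normalization tolerance.
#' @return `params`, invisibly; errors on violation.
#' @export
validate_generation_params <- function(params, tol = 1e-9) {
  chk <- function(x, lab) {
    if (any(x < 0)) stopf("%s has negative entries", lab)
    if (any(abs(rowSums(x) - 1) > tol)) stopf("%s rows do not sum to 1", lab)
  }
  if (abs(sum(params$p_vj) - 1) > tol) stopf("p_vj does not sum to 1")
  if (any(params$p_vj < 0)) stopf("p_vj has negative entries")
  chk(params$p_delv, "p_delv")
  chk(params$p_delj, "p_delj")
  if (abs(sum(params$p_ins) - 1) > tol || any(params$p_ins < 0))
    stopf("p_ins is not a probability vector")
  if (abs(sum(params$ins_init) - 1) > tol || any(params$ins_init < 0))
    stopf("ins_init is not a probability vector")
  chk(params$ins_trans, "ins_trans")
  invisible(params)
}

#' Uniform initial generation parameters
#'
#' Uniform tables over all events allowed by `d_max`/`i_max`; the standard
#' starting point for [fit_generation_model()].
#'
#' @param germline A `germline_set`.
#' @param d_max Maximum deletion count considered per gene end.
#' @param i_max Maximum insertion length.
#' @return A `generation_params` object.
#' @export
init_generation_params <- function(germline, d_max = 12, i_max = 10) {
  nv <- nrow(germline$v); nj <- nrow(germline$j)
  p_vj <- matrix(1 / (nv * nj), nv, nj,
                 dimnames = list(germline$v$name, germline$j$name))
  p_delv <- matrix(1 / (d_max + 1), nv, d_max + 1,
                   dimnames = list(germline$v$name, 0:d_max))
  p_delj <- matrix(1 / (d_max + 1), nj, d_max + 1,
                   dimnames = list(germline$j$name, 0:d_max))
  p_ins <- rep(1 / (i_max + 1), i_max + 1)
  names(p_ins) <- 0:i_max
  ins_init <- rep(0.25, 4); names(ins_init) <- .BASES
  ins_trans <- matrix(0.25, 4, 4, dimnames = list(.BASES, .BASES))
  generation_params(p_vj, p_delv, p_delj, p_ins, ins_init, ins_trans)
}

# Largest deletion count leaving the anchor codon intact, per segment.
max_del_v <- function(germline, d_max) {
  pmin(d_max, nchar(germline$v$seq) - germline$v$anchor - 3L)
}
max_del_j <- function(germline, d_max) {
  pmin(d_max, germline$j$anchor)
}

# Log-probability of inserted strings under the first-order Markov chain.
ins_logprob <- function(strings, ins_init, ins_trans) {
  li <- log(ins_init); lt <- log(ins_trans)
  vapply(strings, function(s) {
    if (nchar(s) == 0) return(0)
    idx <- match(strsplit(s, "")[[1]], .BASES)
    lp <- li[idx[1]]
    if (length(idx) > 1)
      lp <- lp + sum(lt[cbind(idx[-length(idx)], idx[-1])])
    lp
  }, numeric(1), USE.NAMES = FALSE)
}

#' Realize a recombination scenario as a nucleotide sequence
#'
#' Deterministic forward map of the model: the 3'-trimmed V, the inserted
#' junction bases, and the 5'-trimmed J are concatenated.
#'
#' @param scenario One-row data frame (or list) with `v_name`, `j_name`,
#'   `del_v`, `del_j`, `ins_seq`.
#' @param germline A `germline_set`.
#' @return The realized nucleotide string.
#' @export
realize_scenario <- function(scenario, germline) {
  vi <- match(scenario$v_name, germline$v$name)
  ji <- match(scenario$j_name, germline$j$name)
  if (is.na(vi) || is.na(ji)) stopf("unknown gene in scenario")
  vrow <- germline$v[vi, ]; jrow <- germline$j[ji, ]
  if (scenario$del_v < 0 || scenario$del_j < 0) stopf("negative deletion count")
  if (scenario$del_v > nchar(vrow$seq) - vrow$anchor - 3)
    stopf("del_v = %d would remove the conserved V anchor of %s",
          scenario$del_v, vrow$name)
  if (scenario$del_j > jrow$anchor)
    stopf("del_j = %d would remove the conserved J anchor of %s",
          scenario$del_j, jrow$name)
  paste0(substr(vrow$seq, 1, nchar(vrow$seq) - scenario$del_v),
         scenario$ins_seq,
         substr(jrow$seq, scenario$del_j + 1, nchar(jrow$seq)))
}

#' Enumerate all recombination scenarios explaining a read
#'
#' Returns exactly the scenarios whose realization equals the read, bounded
#' by `d_max` deletions per side and `i_max` inserted bases, in deterministic
#' order (V file order, J file order, `del_v` then `del_j` ascending).
#'
#' @param seq Read nucleotide string.
#' @param germline A `germline_set`.
#' @param d_max,i_max Scenario bounds.
#' @return Data frame with columns `v_name`, `j_name`, `del_v`, `del_j`,
#'   `ins_seq` (zero rows when no scenario explains the read).
#' @export
enumerate_scenarios <- function(seq, germline, d_max = 12, i_max = 10) {
  n <- nchar(seq)
  mdv <- max_del_v(germline, d_max)
  mdj <- max_del_j(germline, d_max)
  out <- list()
  for (vi in seq_len(nrow(germline$v))) {
    vseq <- germline$v$seq[vi]; lv <- nchar(vseq)
    for (dv in 0:mdv[vi]) {
      e <- lv - dv                      # V stub length
      if (e > n) next
      if (substr(seq, 1, e) != substr(vseq, 1, e)) next
      for (ji in seq_len(nrow(germline$j))) {
        jseq <- germline$j$seq[ji]; lj <- nchar(jseq)
        for (dj in 0:mdj[ji]) {
          sl <- lj - dj                 # J stub length
          s <- n - sl                   # 0-based start of J stub in read
          if (s < e) next
          if (s - e > i_max) next
          if (substr(seq, s + 1, n) != substr(jseq, dj + 1, lj)) next
          out[[length(out) + 1L]] <- data.frame(
            v_name = germline$v$name[vi], j_name = germline$j$name[ji],
            del_v = dv, del_j = dj,
            ins_seq = substr(seq, e + 1, s), stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(v_name = character(0), j_name = character(0),
                      del_v = integer(0), del_j = integer(0),
                      ins_seq = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(match(res$v_name, germline$v$name),
            match(res$j_name, germline$j$name),
            res$del_v, res$del_j), , drop = FALSE] -> res
  rownames(res) <- NULL
  res
}

# Probability of each scenario row under the model.
scenario_prob <- function(scenarios, params, germline) {
  if (nrow(scenarios) == 0) return(numeric(0))
  vi <- match(scenarios$v_name, rownames(params$p_vj))
  ji <- match(scenarios$j_name, colnames(params$p_vj))
  lp <- log(params$p_vj[cbind(vi, ji)]) +
    log(params$p_delv[cbind(vi, scenarios$del_v + 1L)]) +
    log(params$p_delj[cbind(ji, scenarios$del_j + 1L)]) +
    log(params$p_ins[nchar(scenarios$ins_seq) + 1L]) +
    ins_logprob(scenarios$ins_seq, params$ins_init, params$ins_trans)
  exp(lp)
}

#' Generation probability by exhaustive scenario enumeration
#'
#' Sums the probabilities of every recombination scenario that produces the
#' read. Exact but exponential in the bounds; the reference oracle for
#' [pgen_forward()].
#'
#' @param seq Read nucleotide string.
#' @param params A `generation_params` object.
#' @param germline A `germline_set`.
#' @return A list with `pgen`, `log_pgen` and `n_scenarios`.
#' @export
pgen_brute <- function(seq, params, germline) {
  sc <- enumerate_scenarios(seq, germline, params$d_max, params$i_max)
  p <- sum(scenario_prob(sc, params, germline))
  list(pgen = p, log_pgen = if (p > 0) log(p) else -Inf, n_scenarios = nrow(sc))
}

#' Generation probability by forward dynamic programming
#'
#' Evaluates the same sum as [pgen_brute()] without materializing scenarios:
#' candidate V-stub ends and J-stub starts are located by prefix/suffix
#' matching, and the sum over gene pairs at each junction is a bilinear form
#' in the joint gene-choice table.
#'
#' @inheritParams pgen_brute
#' @return A list with `pgen`, `log_pgen` and `n_scenarios` (`NA`; only the
#'   brute-force path counts scenarios).
#' @export
pgen_forward <- function(seq, params, germline) {
  n <- nchar(seq)
  nv <- nrow(germline$v); nj <- nrow(germline$j)
  mdv <- max_del_v(germline, params$d_max)
  mdj <- max_del_j(germline, params$d_max)

  # candidate V-stub lengths e with read[1..e] == V[1..e]
  vcand <- list()
  for (vi in seq_len(nv)) {
    lv <- nchar(germline$v$seq[vi])
    es <- (lv - mdv[vi]):lv
    es <- es[es >= 1 & es <= n]
    ok <- es[substring(seq, 1, es) == substring(germline$v$seq[vi], 1, es)]
    if (length(ok)) vcand[[length(vcand) + 1L]] <-
        data.frame(vi = vi, e = ok, pd = params$p_delv[vi, lv - ok + 1L])
  }
  jcand <- list()
  for (ji in seq_len(nj)) {
    lj <- nchar(germline$j$seq[ji])
    djs <- 0:mdj[ji]
    sl <- lj - djs
    keep <- sl >= 1 & sl <= n
    djs <- djs[keep]; sl <- sl[keep]
    ok <- substring(seq, n - sl + 1, n) == substring(germline$j$seq[ji], djs + 1, lj)
    if (any(ok)) jcand[[length(jcand) + 1L]] <-
        data.frame(ji = ji, s = n - sl[ok], pd = params$p_delj[ji, djs[ok] + 1L])
  }
  if (length(vcand) == 0 || length(jcand) == 0)
    return(list(pgen = 0, log_pgen = -Inf, n_scenarios = NA_integer_))
  vcand <- do.call(rbind, vcand)
  jcand <- do.call(rbind, jcand)

  # accumulate over junction coordinates (e = V end, s = J start, 0-based)
  total <- 0
  es <- sort(unique(vcand$e))
  ss <- sort(unique(jcand$s))
  for (e in es) {
    ve <- vcand[vcand$e == e, ]
    a <- numeric(nv); a[ve$vi] <- ve$pd
    for (s in ss[ss >= e & ss - e <= params$i_max]) {
      js <- jcand[jcand$s == s, ]
      b <- numeric(nj); b[js$ji] <- js$pd
      gene_sum <- as.numeric(t(a) %*% params$p_vj %*% b)
      if (gene_sum == 0) next
      ins <- substr(seq, e + 1, s)
      total <- total + gene_sum * params$p_ins[s - e + 1L] *
        exp(ins_logprob(ins, params$ins_init, params$ins_trans))
    }
  }
  total <- unname(total)
  list(pgen = total, log_pgen = if (total > 0) log(total) else -Inf,
       n_scenarios = NA_integer_)
}

#' Reference generation parameters for the packaged toy germline
#'
#' A fixed, realistic parameter set used as the simulator default: biased
#' joint V-J usage, per-gene geometric-like deletion profiles over 0..6,
#' a geometric-like insertion-length distribution over 0..`i_max`, and
#' G/C-rich inserted nucleotides (the empirical bias of N insertions).
#'
#' @param germline A `germline_set` (defaults to the packaged toy set).
#' @param i_max Maximum insertion length (default 10).
#' @return A `generation_params` object.
#' @export
toy_generation_params <- function(germline = NULL, i_max = 10) {
  if (is.null(germline))
    germline <- load_germline(system.file("extdata", "toy_germline.fasta",
                                          package = "igkselect"))
  nv <- nrow(germline$v); nj <- nrow(germline$j)
  pv <- c(0.22, 0.18, 0.15, 0.12, 0.10, 0.09, 0.08, 0.06)[seq_len(nv)]
  pj <- c(0.35, 0.30, 0.20, 0.15)[seq_len(nj)]
  pv <- pv / sum(pv); pj <- pj / sum(pj)
  p_vj <- outer(pv, pj)
  # mild deterministic departure from independence (a joint table, as fitted)
  bump <- 1 + 0.2 * sin(outer(seq_len(nv), seq_len(nj), `+`))
  p_vj <- p_vj * bump / sum(p_vj * bump)
  dimnames(p_vj) <- list(germline$v$name, germline$j$name)

  d_max <- 6L
  geo <- function(rate, kmax) { p <- rate^(0:kmax); p / sum(p) }
  rates_v <- seq(0.45, 0.70, length.out = nv)
  rates_j <- seq(0.40, 0.65, length.out = nj)
  p_delv <- t(vapply(rates_v, geo, numeric(d_max + 1), kmax = d_max))
  p_delj <- t(vapply(rates_j, geo, numeric(d_max + 1), kmax = d_max))
  dimnames(p_delv) <- list(germline$v$name, 0:d_max)
  dimnames(p_delj) <- list(germline$j$name, 0:d_max)

  p_ins <- 0.78^(0:i_max); p_ins <- p_ins / sum(p_ins)
  names(p_ins) <- 0:i_max
  ins_init <- c(A = 0.15, C = 0.32, G = 0.38, T = 0.15)
  ins_trans <- rbind(
    A = c(0.22, 0.28, 0.32, 0.18),
    C = c(0.14, 0.36, 0.34, 0.16),
    G = c(0.14, 0.30, 0.40, 0.16),
    T = c(0.20, 0.28, 0.30, 0.22))
  colnames(ins_trans) <- .BASES
  generation_params(p_vj, p_delv, p_delj, p_ins, ins_init, ins_trans)
}
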