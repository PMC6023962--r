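# EM inference of the generation model from out-of-frame reads.
#
# The hidden variable of each read is its recombination scenario. Because a
# read determines its inserted bases once the junction boundaries are fixed,
# the E-step reduces to a posterior over (V, delV, J, delJ) boundary pairs;
# these are enumerated once per read by prefix/suffix matching and reused
# across iterations, so each EM sweep is a handful of vectorized operations
# over one long scenario table.

# Build the per-read scenario table shared by all EM iterations.
build_scenario_table <- function(seqs, germline, d_max, i_max) {
  n_reads <- length(seqs)
  ns <- nchar(seqs)
  mdv <- max_del_v(germline, d_max)
  mdj <- max_del_j(germline, d_max)

  vparts <- list()
  for (vi in seq_len(nrow(germline$v))) {
    vseq <- germline$v$seq[vi]; lv <- nchar(vseq)
    for (e in (lv - mdv[vi]):lv) {
      hit <- which(ns >= e & substring(seqs, 1, e) == substr(vseq, 1, e))
      if (length(hit))
        vparts[[length(vparts) + 1L]] <- data.frame(read = hit, vi = vi,
                                                    e = e, del_v = lv - e)
    }
  }
  jparts <- list()
  for (ji in seq_len(nrow(germline$j))) {
    jseq <- germline$j$seq[ji]; lj <- nchar(jseq)
    for (dj in 0:mdj[ji]) {
      sl <- lj - dj
      stub <- substr(jseq, dj + 1, lj)
      hit <- which(ns >= sl & substring(seqs, ns - sl + 1, ns) == stub)
      if (length(hit))
        jparts[[length(jparts) + 1L]] <- data.frame(read = hit, ji = ji,
                                                    s = ns[hit] - sl, del_j = dj)
    }
  }
  if (length(vparts) == 0 || length(jparts) == 0) {
    return(list(tab = NULL, n_reads = n_reads, covered = integer(0)))
  }
  vtab <- do.call(rbind, vparts)
  jtab <- do.call(rbind, jparts)
  tab <- merge(vtab, jtab, by = "read")
  tab <- tab[tab$s >= tab$e & tab$s - tab$e <= i_max, , drop = FALSE]
  if (nrow(tab) == 0) return(list(tab = NULL, n_reads = n_reads, covered = integer(0)))
  tab$ins_len <- tab$s - tab$e
  ins <- substring(seqs[tab$read], tab$e + 1, tab$s)
  uf <- factor(ins)
  tab$ins_code <- as.integer(uf)
  ulev <- levels(uf)

  # per-unique-insertion sufficient statistics: first base (4) + transitions (16)
  C <- matrix(0, length(ulev), 20L)
  for (u in seq_along(ulev)) {
    s <- ulev[u]
    if (nchar(s) == 0) next
    idx <- match(strsplit(s, "")[[1]], .BASES)
    C[u, idx[1]] <- 1
    if (length(idx) > 1) {
      pair <- 4L + (idx[-length(idx)] - 1L) * 4L + idx[-1]
      tp <- tabulate(pair, 20L)
      C[u, ] <- C[u, ] + tp
    }
  }
  tab <- tab[order(tab$read), , drop = FALSE]
  list(tab = tab, ins_stats = C, n_reads = n_reads,
       covered = sort(unique(tab$read)))
}

# One E-step + sufficient statistics given current parameters.
em_estep <- function(st, params) {
  tab <- st$tab
  clog <- function(x) {                 # -Inf would give 0 * -Inf = NaN in %*%
    y <- log(x)
    y[!is.finite(y)] <- -745
    y
  }
  lw <- log(params$p_vj)[cbind(tab$vi, tab$ji)] +
    log(params$p_delv)[cbind(tab$vi, tab$del_v + 1L)] +
    log(params$p_delj)[cbind(tab$ji, tab$del_j + 1L)] +
    log(params$p_ins)[tab$ins_len + 1L] +
    (st$ins_stats %*% c(clog(params$ins_init),
                        as.vector(t(clog(params$ins_trans)))))[tab$ins_code]
  w <- exp(lw)
  denom <- rowsum(w, tab$read, reorder = TRUE)
  dead <- denom[, 1] == 0
  if (any(dead)) stopf("numerical underflow: %d reads lost all scenario mass",
                       sum(dead))
  wn <- w / denom[match(tab$read, as.integer(rownames(denom))), 1]
  list(w = wn, loglik = sum(log(denom[, 1])))
}

# Enumeration of junction-length cells for the frame-ascertainment
# correction: whether a scenario realizes in-frame depends only on
# (V, J, delV, delJ, insertion length).
build_frame_cells <- function(germline, d_max, i_max) {
  mdv <- max_del_v(germline, d_max)
  mdj <- max_del_j(germline, d_max)
  cells <- list()
  for (vi in seq_len(nrow(germline$v))) for (ji in seq_len(nrow(germline$j))) {
    grid <- expand.grid(dv = 0:mdv[vi], dj = 0:mdj[ji], k = 0:i_max)
    lv <- nchar(germline$v$seq[vi]); av <- germline$v$anchor[vi]
    aj <- germline$j$anchor[ji]
    span <- (lv - av - grid$dv) + grid$k + (aj - grid$dj) + 3L
    cells[[length(cells) + 1L]] <- data.frame(vi = vi, ji = ji, grid,
                                              inframe = span %% 3L == 0L)
  }
  do.call(rbind, cells)
}

# Expected sufficient statistics of the unobserved in-frame draws, for the
# truncated-sample EM: an out-of-frame pool is an ascertained sample, and
# the complete-data likelihood adds n_obs * P(IF)/P(OF) phantom draws whose
# statistics are conditional expectations under the current parameters.
frame_augmentation <- function(cells, params, n_obs) {
  nv <- nrow(params$p_vj); nj <- ncol(params$p_vj)
  cw <- params$p_vj[cbind(cells$vi, cells$ji)] *
    params$p_delv[cbind(cells$vi, cells$dv + 1L)] *
    params$p_delj[cbind(cells$ji, cells$dj + 1L)] *
    params$p_ins[cells$k + 1L]
  p_if <- sum(cw[cells$inframe])
  p_of <- sum(cw[!cells$inframe])
  if (p_of <= 0) stopf("model assigns no mass to out-of-frame products")
  scale <- n_obs * p_if / p_of
  wif <- numeric(nrow(cells))
  wif[cells$inframe] <- cw[cells$inframe] / p_if * scale
  accum <- function(code, size) {
    out <- numeric(size)
    s <- rowsum(wif, code, reorder = TRUE)
    out[as.integer(rownames(s))] <- s[, 1]
    out
  }
  k_w <- accum(cells$k + 1L, params$i_max + 1L)
  # expected inserted-nucleotide statistics given insertion length
  exp_init <- sum(k_w[-1]) * params$ins_init
  exp_trans <- matrix(0, 4, 4)
  pi_t <- params$ins_init
  step <- matrix(0, 4, 4)
  for (k in seq_len(params$i_max)) {
    if (k >= 2) {
      step <- step + pi_t * params$ins_trans
      pi_t <- as.vector(pi_t %*% params$ins_trans)
    }
    exp_trans <- exp_trans + k_w[k + 1L] * step
  }
  list(cvj = accum((cells$ji - 1L) * nv + cells$vi, nv * nj),
       cdv = accum(cells$dv * nv + cells$vi, nv * (params$d_max + 1L)),
       cdj = accum(cells$dj * nj + cells$ji, nj * (params$d_max + 1L)),
       cins = k_w, init = exp_init, trans = exp_trans,
       p_of = p_of, p_if = p_if)
}

# M-step: reassemble normalized tables from expected counts.
em_mstep <- function(st, w, params, pseudocount = 0, aug = NULL) {
  tab <- st$tab
  nv <- nrow(params$p_vj); nj <- ncol(params$p_vj)
  dmax <- params$d_max; imax <- params$i_max
  norm_rows <- function(m) {
    tot <- rowSums(m)
    bad <- tot == 0
    m[bad, ] <- 1 / ncol(m)         # unused conditional rows stay uniform
    tot[bad] <- 1
    m / tot
  }
  acc <- function(code, size) {
    out <- numeric(size)
    s <- rowsum(w, code, reorder = TRUE)
    out[as.integer(rownames(s))] <- s[, 1]
    out + pseudocount
  }
  cvj <- acc((tab$ji - 1L) * nv + tab$vi, nv * nj)
  cdv <- acc((tab$del_v) * nv + tab$vi, nv * (dmax + 1L))
  cdj <- acc((tab$del_j) * nj + tab$ji, nj * (dmax + 1L))
  cins <- acc(tab$ins_len + 1L, imax + 1L)
  if (!is.null(aug)) {
    cvj <- cvj + aug$cvj
    cdv <- cdv + aug$cdv
    cdj <- cdj + aug$cdj
    cins <- cins + aug$cins
  }
  p_vj <- matrix(cvj / sum(cvj), nv, nj, dimnames = dimnames(params$p_vj))
  p_delv <- norm_rows(matrix(cdv, nv, dmax + 1L, dimnames = dimnames(params$p_delv)))
  p_delj <- norm_rows(matrix(cdj, nj, dmax + 1L, dimnames = dimnames(params$p_delj)))
  p_ins <- cins / sum(cins)
  names(p_ins) <- 0:imax

  wu <- numeric(nrow(st$ins_stats))
  s <- rowsum(w, tab$ins_code, reorder = TRUE)
  wu[as.integer(rownames(s))] <- s[, 1]
  counts <- as.vector(t(st$ins_stats) %*% wu) + pseudocount
  ini <- counts[1:4]
  tr <- matrix(counts[5:20], 4, 4, byrow = TRUE, dimnames = list(.BASES, .BASES))
  if (!is.null(aug)) {
    ini <- ini + aug$init
    tr <- tr + aug$trans
  }
  ins_init <- if (sum(ini) > 0) ini / sum(ini) else params$ins_init
  names(ins_init) <- .BASES
  ins_trans <- norm_rows(tr)
  out <- params
  out$p_vj <- p_vj; out$p_delv <- p_delv; out$p_delj <- p_delj
  out$p_ins <- p_ins; out$ins_init <- ins_init; out$ins_trans <- ins_trans
  out
}

#' Fit the generation model to out-of-frame reads by EM
#'
#' Maximum-likelihood inference of the recombination parameters from
#' unselected (out-of-frame) reads. Each read's likelihood sums over every
#' recombination scenario consistent with it; the E-step computes exact
#' scenario posteriors from a precomputed junction table and the M-step
#' re-normalizes expected event counts. The total log-likelihood is
#' non-decreasing across iterations.
#'
#' @param reads Character vector of read sequences, or a data frame with a
#'   `seq` column (as returned by [read_repertoire()] or [simulate_pool()]).
#' @param germline A `germline_set`.
#' @param d_max,i_max Scenario bounds (maximum deletions per side, maximum
#'   insertion length).
#' @param tol Stop when the total log-likelihood gain falls below this.
#' @param max_iter Iteration cap.
#' @param init Optional `generation_params` starting point (default uniform).
#' @param pseudocount Optional count added to every event in the M-step to
#'   avoid absorbing zeros (0 = off, the default).
#' @param frame_correction Account for the out-of-frame ascertainment of the
#'   sample (default `TRUE`). An out-of-frame pool is a truncated sample of
#'   the generation process: whether a rearrangement falls out of frame
#'   depends on its junction lengths, so fitting the unconditional model to
#'   such a pool biases the deletion and insertion-length tables. The
#'   corrected E-step adds the expected sufficient statistics of the
#'   unobserved in-frame draws, giving the maximum-likelihood estimate under
#'   the ascertainment. Set `FALSE` when the reads are not frame-filtered.
#' @param verbose Print per-iteration log-likelihoods.
#' @return An object of class `generation_model` with elements `params`
#'   (`generation_params`), `logLik_trace` (the ascertainment-conditional
#'   log-likelihood when `frame_correction` is on), `n_used`, `n_excluded`,
#'   `converged`, `n_iter`.
#' @export
fit_generation_model <- function(reads, germline, d_max = 12, i_max = 10,
                                 tol = 1e-6, max_iter = 200, init = NULL,
                                 pseudocount = 0, frame_correction = TRUE,
                                 verbose = FALSE) {
  seqs <- if (is.data.frame(reads)) reads$seq else as.character(reads)
  if (length(seqs) == 0) stopf("no reads supplied")
  st <- build_scenario_table(seqs, germline, d_max, i_max)
  n_excluded <- st$n_reads - length(st$covered)
  if (length(st$covered) == 0)
    stopf("no read is explained by any scenario under d_max=%d, i_max=%d",
          d_max, i_max)
  if (n_excluded > 0)
    message(sprintf("excluded %d/%d reads with no consistent scenario",
                    n_excluded, st$n_reads))
  params <- init %||% init_generation_params(germline, d_max, i_max)
  validate_generation_params(params)
  cells <- if (frame_correction) build_frame_cells(germline, d_max, i_max)

  trace <- numeric(0)
  converged <- FALSE
  n_used <- length(st$covered)
  for (it in seq_len(max_iter)) {
    e <- em_estep(st, params)
    aug <- NULL
    ll <- e$loglik
    if (frame_correction) {
      aug <- frame_augmentation(cells, params, n_used)
      ll <- ll - n_used * log(aug$p_of)
    }
    trace <- c(trace, ll)
    if (verbose) message(sprintf("iter %3d  logLik %.6f", it, ll))
    params <- em_mstep(st, e$w, params, pseudocount, aug)
    if (it > 1 && trace[it] - trace[it - 1] < tol) { converged <- TRUE; break }
  }
  validate_generation_params(params, tol = 1e-6)
  out <- list(params = params, germline = germline, logLik_trace = trace,
              n_used = length(st$covered), n_excluded = n_excluded,
              converged = converged, n_iter = length(trace),
              call = match.call())
  class(out) <- "generation_model"
  out
}

#' @export
print.generation_model <- function(x, ...) {
  cat("VJ-recombination generation model\n")
  cat(sprintf("  genes: %d V x %d J; d_max = %d, i_max = %d\n",
              nrow(x$params$p_vj), ncol(x$params$p_vj),
              x$params$d_max, x$params$i_max))
  cat(sprintf("  fitted on %d reads (%d excluded), %d EM iterations%s\n",
              x$n_used, x$n_excluded, x$n_iter,
              if (x$converged) ", converged" else " (not converged)"))
  cat(sprintf("  logLik: %.3f\n", utils::tail(x$logLik_trace, 1)))
  invisible(x)
}

#' @export
#' @method summary generation_model
summary.generation_model <- function(object, ...) {
  p <- object$params
  cat("Marginal V usage:\n"); print(round(rowSums(p$p_vj), 4))
  cat("Marginal J usage:\n"); print(round(colSums(p$p_vj), 4))
  cat("Insertion-length distribution:\n"); print(round(p$p_ins, 4))
  cat("Mean deletions: V", round(sum(colSums(p$p_delv * rowSums(p$p_vj)) *
                                       (0:p$d_max)), 3),
      " J", round(sum(colSums(p$p_delj * colSums(p$p_vj)) * (0:p$d_max)), 3), "\n")
  invisible(object)
}

#' @export
#' @method coef generation_model
coef.generation_model <- function(object, ...) object$params

#' @export
#' @method logLik generation_model
logLik.generation_model <- function(object, ...) {
  ll <- utils::tail(object$logLik_trace, 1)
  attr(ll, "nobs") <- object$n_used
  class(ll) <- "logLik"
  ll
}

#' Per-read generation probabilities from a fitted model
#'
#' @param object A `generation_model`.
#' @param newdata Character vector of sequences or data frame with `seq`.
#' @param method `"forward"` (dynamic programming, default) or `"brute"`
#'   (exhaustive enumeration).
#' @param ... Unused.
#' @return Numeric vector of Pgen values (0 for unexplainable reads).
#' @export
predict.generation_model <- function(object, newdata,
                                     method = c("forward", "brute"), ...) {
  method <- match.arg(method)
  seqs <- if (is.data.frame(newdata)) newdata$seq else as.character(newdata)
  f <- if (method == "forward") pgen_forward else pgen_brute
  vapply(seqs, function(s) f(s, object$params, object$germline)$pgen,
         numeric(1), USE.NAMES = FALSE)
}
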