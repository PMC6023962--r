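# The factorized CDR3 selection model
#   Q(V, J, a_1..a_L) = q(V,J) q_L prod_i q_{i;L}(a_i) / z,
# inferred by matching the marginals of the Q-reweighted pre-selection
# ensemble to the marginals of the productive (in-frame) data. Factors are
# reported under the convention that the expected factor of every family
# under the pre-selection ensemble is 1, so log q > 0 reads as positive and
# log q < 0 as negative selection; z makes E_pre[Q] = 1.

# Long position table: one row per (observation, CDR3 position).
features_long <- function(features, L_max, what = c("aa", "codon")) {
  what <- match.arg(what)
  L <- nchar(features$cdr3_aa)
  if (any(L < 1)) stopf("empty CDR3 in features")
  if (any(L > L_max)) stopf("%d features exceed L_max = %d (filter first)",
                            sum(L > L_max), L_max)
  if (what == "aa") {
    sym <- strsplit(paste(features$cdr3_aa, collapse = ""), "")[[1]]
    code <- match(sym, .AA20)
    if (anyNA(code)) stopf("non-standard amino acid in CDR3: %s",
                           sym[is.na(code)][1])
    nsym <- 20L
  } else {
    if (is.null(features$cdr3_nt)) stopf("codon granularity needs cdr3_nt")
    cods <- unlist(split_codons(features$cdr3_nt), use.names = FALSE)
    code <- match(cods, names(.GENETIC_CODE))
    if (anyNA(code)) stopf("bad codon in cdr3_nt")
    nsym <- 64L
  }
  obs <- rep(seq_along(L), L)
  pos <- sequence(L)
  list(obs = obs, cell = pos + L_max * (rep(L, L) - 1L) +
         as.integer(L_max)^2 * (code - 1L),
       L = L, nsym = nsym)
}

# Observation weights Q (up to z) under the current factors.
model_weights <- function(st, q_vj_flat, q_len, lq_pos_flat) {
  lp <- rowsum(lq_pos_flat[st$long$cell], st$long$obs, reorder = TRUE)[, 1]
  lv <- log(q_vj_flat[st$vj_code]); lv[is.na(lv)] <- 0
  ll <- log(q_len[st$L]); ll[is.na(ll)] <- 0
  exp(lv + ll + lp)
}

cell_marginal <- function(long, w_obs, ncell) {
  m <- numeric(ncell)
  s <- rowsum(w_obs[long$obs], long$cell, reorder = TRUE)
  m[as.integer(rownames(s))] <- s[, 1]
  m / sum(w_obs)
}

vec_marginal <- function(code, w_obs, ncode) {
  m <- numeric(ncode)
  s <- rowsum(w_obs, code, reorder = TRUE)
  m[as.integer(rownames(s))] <- s[, 1]
  m / sum(w_obs)
}

prep_side <- function(features, germline_names, L_max, what = "aa") {
  vi <- match(features$v_name, germline_names$v)
  ji <- match(features$j_name, germline_names$j)
  if (anyNA(vi) || anyNA(ji)) stopf("feature uses a gene absent from the model")
  long <- features_long(features, L_max, what)
  list(long = long, vi = vi, ji = ji,
       vj_code = (ji - 1L) * length(germline_names$v) + vi,
       L = long$L, n = nrow(features))
}

#' Fit the factorized selection model
#'
#' Infers multiplicative selection factors by iterative proportional fitting:
#' each sweep rescales one factor family by the ratio of the data marginal to
#' the marginal of the Q-reweighted pre-selection sample, which converges to
#' the fixed point where all three factor families reproduce the in-frame
#' marginals. Factors are estimated only for cells observed at least
#' `min_count` times in both ensembles; other cells are left undefined
#' (excluded from products, reported in `diagnostics`).
#'
#' @param if_features In-frame (productive) feature data frame with columns
#'   `v_name`, `j_name`, `cdr3_aa` (and `cdr3_nt` for codon granularity),
#'   e.g. from [extract_cdr3()] or [simulate_pool()].
#' @param pre Pre-selection sample from [sample_pre_repertoire()].
#' @param L_max Maximum CDR3 length modelled (default 19).
#' @param tol Convergence threshold on the largest absolute difference
#'   between data and model marginal entries.
#' @param max_iter Sweep cap.
#' @param min_count Minimum per-cell observation count (both ensembles) for a
#'   factor to be estimated.
#' @param granularity `"amino_acid"`, or `"codon"` to additionally compute
#'   codon-level factors by one re-estimation pass at the amino-acid fixed
#'   point.
#' @return An object of class `selection_model` with factor tables `q_vj`,
#'   `q_len`, `q_pos` (position x length x amino acid; `NA` = undefined),
#'   optionally `q_codon`, the normalization `z`, pre/data marginals, and
#'   fitting diagnostics.
#' @export
fit_selection_model <- function(if_features, pre, L_max = 19, tol = 1e-3,
                                max_iter = 100, min_count = 50,
                                granularity = c("amino_acid", "codon")) {
  granularity <- match.arg(granularity)
  if (nrow(if_features) == 0 || nrow(pre) == 0) stopf("empty input")
  if (nrow(pre) < 5 * nrow(if_features))
    warnf("pre-selection sample is less than 5x the in-frame data (%d vs %d)",
          nrow(pre), nrow(if_features))
  gl <- list(v = sort(unique(pre$v_name)), j = sort(unique(pre$j_name)))
  keepL <- function(x) x[nchar(x$cdr3_aa) >= 1 & nchar(x$cdr3_aa) <= L_max, ,
                         drop = FALSE]
  n0 <- nrow(if_features)
  if_features <- keepL(if_features); pre <- keepL(pre)
  if (nrow(if_features) < n0)
    message(sprintf("dropped %d in-frame features outside 1..L_max", n0 - nrow(if_features)))
  if_features <- if_features[if_features$v_name %in% gl$v &
                               if_features$j_name %in% gl$j, , drop = FALSE]

  dat <- prep_side(if_features, gl, L_max)
  prs <- prep_side(pre, gl, L_max)
  nv <- length(gl$v); nj <- length(gl$j)
  ncell <- as.integer(L_max)^2 * 20L

  w1 <- rep(1, prs$n)
  cnt_d_cell <- cell_marginal(dat$long, rep(1, dat$n), ncell) * dat$n
  cnt_p_cell <- cell_marginal(prs$long, w1, ncell) * prs$n
  cnt_d_vj <- vec_marginal(dat$vj_code, rep(1, dat$n), nv * nj) * dat$n
  cnt_p_vj <- vec_marginal(prs$vj_code, w1, nv * nj) * prs$n
  cnt_d_L <- vec_marginal(dat$L, rep(1, dat$n), L_max) * dat$n
  cnt_p_L <- vec_marginal(prs$L, w1, L_max) * prs$n

  def_cell <- cnt_d_cell >= min_count & cnt_p_cell >= min_count
  def_vj <- cnt_d_vj >= min_count & cnt_p_vj >= min_count
  def_L <- cnt_d_L >= min_count & cnt_p_L >= min_count
  md_cell <- cnt_d_cell / dat$n
  md_vj <- cnt_d_vj / dat$n
  md_L <- cnt_d_L / dat$n

  q_vj <- ifelse(def_vj, 1, NA_real_)
  q_len <- ifelse(def_L, 1, NA_real_)
  q_cell <- ifelse(def_cell, 1, NA_real_)

  # iterative proportional fitting: one margin family at a time (gene pair,
  # length, then each CDR3 position), with incremental weight updates --
  # positions of one sequence are coupled margins and must not be rescaled
  # in a single joint step
  lq <- function(x) { y <- log(x); y[is.na(y)] <- 0; y }
  pos_of_cell <- (seq_len(ncell) - 1L) %% L_max + 1L
  long_pos <- pos_of_cell[prs$long$cell]
  pos_rows <- split(seq_along(prs$long$cell), long_pos)
  w <- rep(1, prs$n)
  ratio_or_1 <- function(num, den, def) {
    r <- rep(1, length(num))
    r[def] <- num[def] / den[def]
    r
  }
  delta <- Inf; it <- 0
  while (it < max_iter) {
    it <- it + 1
    mm_vj <- vec_marginal(prs$vj_code, w, nv * nj)
    r <- ratio_or_1(md_vj, mm_vj, def_vj)
    q_vj[def_vj] <- q_vj[def_vj] * r[def_vj]
    w <- w * r[prs$vj_code]

    mm_L <- vec_marginal(prs$L, w, L_max)
    r <- ratio_or_1(md_L, mm_L, def_L)
    q_len[def_L] <- q_len[def_L] * r[def_L]
    w <- w * r[prs$L]

    for (i in as.integer(names(pos_rows))) {
      rows <- pos_rows[[as.character(i)]]
      mm_i <- numeric(ncell)
      sm <- rowsum(w[prs$long$obs[rows]], prs$long$cell[rows], reorder = TRUE)
      mm_i[as.integer(rownames(sm))] <- sm[, 1]
      mm_i <- mm_i / sum(w)
      def_i <- def_cell & pos_of_cell == i
      r <- ratio_or_1(md_cell, mm_i, def_i)
      q_cell[def_i] <- q_cell[def_i] * r[def_i]
      w[prs$long$obs[rows]] <- w[prs$long$obs[rows]] * r[prs$long$cell[rows]]
    }

    if (any(!is.finite(q_vj[def_vj])) || any(!is.finite(q_cell[def_cell])) ||
        any(!is.finite(q_len[def_L])))
      stopf("selection factors overflowed at sweep %d", it)

    mm_vj <- vec_marginal(prs$vj_code, w, nv * nj)
    mm_L <- vec_marginal(prs$L, w, L_max)
    mm_cell <- cell_marginal(prs$long, w, ncell)
    delta <- max(abs(md_vj - mm_vj)[def_vj], abs(md_L - mm_L)[def_L],
                 abs(md_cell - mm_cell)[def_cell])
    if (delta < tol) break
  }

  # sign convention: expected factor 1 under the pre-selection ensemble,
  # per (i, L) for position factors, globally for q_len and q_vj
  q_tilde <- ifelse(is.na(q_cell), 1, q_cell)
  dim3 <- c(L_max, L_max, 20L)
  cnt_arr <- array(cnt_p_cell, dim3)
  qt_arr <- array(q_tilde, dim3)
  s_il <- apply(cnt_arr * qt_arr, c(1, 2), sum) /
    pmax(apply(cnt_arr, c(1, 2), sum), .Machine$double.xmin)
  s_il[apply(cnt_arr, c(1, 2), sum) == 0] <- 1
  q_cell <- as.vector(array(q_cell, dim3) / as.vector(s_il))
  for (Lv in seq_len(L_max)) {
    if (!is.na(q_len[Lv])) q_len[Lv] <- q_len[Lv] * prod(s_il[seq_len(Lv), Lv])
  }
  pre_L <- cnt_p_L / sum(cnt_p_L)
  tL <- sum(pre_L * ifelse(is.na(q_len), 1, q_len))
  q_len <- q_len / tL
  pre_vj <- cnt_p_vj / sum(cnt_p_vj)
  tV <- sum(pre_vj * ifelse(is.na(q_vj), 1, q_vj))
  q_vj <- q_vj / tV

  w <- model_weights(prs, q_vj, q_len, lq(q_cell))
  z <- mean(w)

  model <- list(
    q_vj = matrix(q_vj, nv, nj, dimnames = list(gl$v, gl$j)),
    q_len = stats::setNames(q_len, seq_len(L_max)),
    q_pos = array(q_cell, dim3,
                  dimnames = list(pos = seq_len(L_max), len = seq_len(L_max),
                                  aa = .AA20)),
    z = z, L_max = L_max, granularity = "amino_acid",
    genes = gl,
    pre_marginals = list(cell = cnt_p_cell / prs$n, vj = pre_vj, L = pre_L),
    data_marginals = list(cell = md_cell, vj = md_vj, L = md_L),
    diagnostics = list(
      n_iter = it, max_marginal_gap = delta, converged = delta < tol,
      n_if = dat$n, n_pre = prs$n, min_count = min_count,
      n_undefined_cells = sum(cnt_d_cell >= min_count & cnt_p_cell < min_count)))
  class(model) <- "selection_model"
  if (granularity == "codon")
    model <- estimate_codon_factors(model, if_features, pre)
  model
}

#' Codon-level selection factors at the amino-acid fixed point
#'
#' Re-estimates factors at codon granularity by a single marginal-ratio pass
#' with the fitted amino-acid model held fixed: each codon factor is its
#' amino acid's factor times the data/model ratio of the codon's marginal,
#' so synonymous codons share a factor exactly when their usage is unchanged
#' by selection.
#'
#' @param model A fitted `selection_model`.
#' @param if_features,pre The same feature sets used in the fit, with
#'   `cdr3_nt` present.
#' @return The model with a `q_codon` array (position x length x codon) and
#'   `granularity = "codon"`.
#' @export
estimate_codon_factors <- function(model, if_features, pre) {
  L_max <- model$L_max
  keepL <- function(x) x[nchar(x$cdr3_aa) >= 1 & nchar(x$cdr3_aa) <= L_max, ,
                         drop = FALSE]
  if_features <- keepL(if_features); pre <- keepL(pre)
  if_features <- if_features[if_features$v_name %in% model$genes$v &
                               if_features$j_name %in% model$genes$j, , drop = FALSE]
  dat <- prep_side(if_features, model$genes, L_max, what = "codon")
  prs <- prep_side(pre, model$genes, L_max, what = "codon")
  ncell <- as.integer(L_max)^2 * 64L
  w <- selection_weights(model, pre)
  cnt_d <- cell_marginal(dat$long, rep(1, dat$n), ncell) * dat$n
  cnt_p_w <- cell_marginal(prs$long, w, ncell)
  cnt_p_raw <- cell_marginal(prs$long, rep(1, prs$n), ncell) * prs$n
  def <- cnt_d >= model$diagnostics$min_count &
    cnt_p_raw >= model$diagnostics$min_count
  md <- cnt_d / dat$n
  aa_of_codon <- match(.GENETIC_CODE, .AA20)   # NA for stop codons
  dimc <- c(L_max, L_max, 64L)
  idx <- arrayInd(seq_len(ncell), dimc)
  q_aa_flat <- model$q_pos[cbind(idx[, 1], idx[, 2], aa_of_codon[idx[, 3]])]
  q_codon <- rep(NA_real_, ncell)
  ok <- def & !is.na(q_aa_flat) & cnt_p_w > 0
  q_codon[ok] <- q_aa_flat[ok] * md[ok] / (cnt_p_w[ok] / 1)
  # cnt_p_w is already Q-weighted and normalized; md/cnt_p_w is the residual
  model$q_codon <- array(q_codon, dimc,
                         dimnames = list(pos = seq_len(L_max),
                                         len = seq_len(L_max),
                                         codon = names(.GENETIC_CODE)))
  model$pre_marginals$codon <- cnt_p_raw / prs$n
  model$granularity <- "codon"
  model
}

# Q weight (unnormalized by z) of each feature row under the model.
selection_weights <- function(model, features) {
  st <- prep_side(features, model$genes, model$L_max)
  lqp <- log(model$q_pos); lqp[is.na(lqp)] <- 0
  model_weights(st, as.vector(model$q_vj), model$q_len, as.vector(lqp))
}

#' Selection factor Q of feature tuples
#'
#' Evaluates Q = q(V,J) q_L prod_i q_{i;L}(a_i) / z for each row; undefined
#' factors are excluded from the product.
#'
#' @param features Data frame with `v_name`, `j_name`, `cdr3_aa`.
#' @param model A fitted `selection_model`.
#' @param unknown `"error"` (default) to fail on genes or lengths outside the
#'   model, or `"floor"` to return `floor` for such rows.
#' @param floor Value returned for unknown rows when `unknown = "floor"`.
#' @return Numeric vector of selection factors.
#' @export
sequence_q <- function(features, model, unknown = c("error", "floor"),
                       floor = 0) {
  unknown <- match.arg(unknown)
  known <- features$v_name %in% model$genes$v &
    features$j_name %in% model$genes$j &
    nchar(features$cdr3_aa) >= 1 & nchar(features$cdr3_aa) <= model$L_max
  if (!all(known)) {
    if (unknown == "error")
      stopf("%d features have a gene or CDR3 length outside the model",
            sum(!known))
    out <- rep(floor, nrow(features))
    if (any(known))
      out[known] <- sequence_q(features[known, , drop = FALSE], model)
    return(out)
  }
  unname(selection_weights(model, features) / model$z)
}

#' Length-averaged log selection factors
#'
#' Averages each factor over the CDR3 lengths where it is defined and
#' returns the log: entries above 0 indicate positive, below 0 negative
#' selection. Symbols with no defined length anywhere are `NA` (rendered
#' blank in heatmaps).
#'
#' @param model A fitted `selection_model`.
#' @param granularity `"amino_acid"` or `"codon"` (needs codon factors).
#' @return For amino acids, a symbol x position matrix of log mean factors.
#'   For codons, a list with the codon-level matrix (`codon`) and the
#'   per-amino-acid aggregate (`aa`, log of the mean over the amino acid's
#'   codons).
#' @export
average_log_q <- function(model, granularity = c("amino_acid", "codon")) {
  granularity <- match.arg(granularity)
  avg_over_L <- function(arr) {
    out <- apply(arr, c(3, 1), function(v) {
      if (all(is.na(v))) NA_real_ else log(mean(v, na.rm = TRUE))
    })
    colnames(out) <- seq_len(dim(arr)[1])
    out
  }
  if (granularity == "amino_acid") return(avg_over_L(model$q_pos))
  if (is.null(model$q_codon)) stopf("model has no codon-level factors")
  codon_tab <- avg_over_L(model$q_codon)
  aa_mean <- t(vapply(.AA20, function(a) {
    rows <- which(.GENETIC_CODE == a)
    sub <- exp(codon_tab[rows, , drop = FALSE])
    apply(sub, 2, function(v) if (all(is.na(v))) NA_real_
          else log(mean(v, na.rm = TRUE)))
  }, numeric(ncol(codon_tab))))
  list(codon = codon_tab, aa = aa_mean)
}

#' Post-selection feature probabilities
#'
#' @param features Feature data frame.
#' @param model A fitted `selection_model`.
#' @param p_pre Pre-selection probabilities of the rows (exact on toy models
#'   or Monte-Carlo feature frequencies).
#' @return Data frame with `p_pre`, `q` and `p_post = q * p_pre`.
#' @export
p_post <- function(features, model, p_pre) {
  if (length(p_pre) != nrow(features)) stopf("p_pre length mismatch")
  q <- sequence_q(features, model)
  if (any(p_pre == 0 & q > 0))
    stopf("p_post undefined: q > 0 with p_pre = 0")
  data.frame(p_pre = p_pre, q = q, p_post = q * p_pre)
}

#' @export
print.selection_model <- function(x, ...) {
  cat("Factorized CDR3 selection model\n")
  cat(sprintf("  granularity: %s; L_max = %d; z = %.4f\n",
              x$granularity, x$L_max, x$z))
  cat(sprintf("  defined factors: %d (V,J), %d lengths, %d position cells\n",
              sum(!is.na(x$q_vj)), sum(!is.na(x$q_len)), sum(!is.na(x$q_pos))))
  d <- x$diagnostics
  cat(sprintf("  fit: %d sweeps, max marginal gap %.2e (%s); n_if = %d, n_pre = %d\n",
              d$n_iter, d$max_marginal_gap,
              if (d$converged) "converged" else "not converged", d$n_if, d$n_pre))
  invisible(x)
}

#' @export
#' @method summary selection_model
summary.selection_model <- function(object, ...) {
  print(object)
  alq <- average_log_q(object)
  agg <- apply(alq, 1, function(v) if (all(is.na(v))) NA_real_
               else mean(v, na.rm = TRUE))
  agg <- sort(agg[!is.na(agg)], decreasing = TRUE)
  cat("Mean log selection factor by amino acid (over positions):\n")
  print(round(agg, 3))
  invisible(object)
}

#' @export
#' @method coef selection_model
coef.selection_model <- function(object, ...) {
  list(q_vj = object$q_vj, q_len = object$q_len, q_pos = object$q_pos,
       q_codon = object$q_codon, z = object$z)
}

#' @export
predict.selection_model <- function(object, newdata, ...) {
  sequence_q(newdata, object, ...)
}

#' Heatmap of length-averaged log selection factors
#'
#' @param x A fitted `selection_model`.
#' @param ... Passed to [graphics::image()].
#' @return The plotted matrix, invisibly.
#' @export
#' @method plot selection_model
plot.selection_model <- function(x, ...) {
  m <- average_log_q(x)
  mm <- max(abs(m), na.rm = TRUE)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(-mm, mm),
                  col = grDevices::hcl.colors(51, "Blue-Red 3", rev = TRUE),
                  xlab = "CDR3 position", ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rownames(m), las = 2,
                 cex.axis = 0.7)
  invisible(m)
}
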