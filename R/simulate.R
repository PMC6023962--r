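# Synthetic repertoires: the generation model run forwards, productivity
# classification, acceptance-rejection selection by Q, and clonal families
# grown by point mutation.

# Vectorized draw of n recombination scenarios from the model.
draw_scenarios <- function(params, germline, n) {
  nv <- nrow(params$p_vj); nj <- ncol(params$p_vj)
  vj <- sample.int(nv * nj, n, replace = TRUE, prob = as.vector(params$p_vj))
  vi <- (vj - 1L) %% nv + 1L
  ji <- (vj - 1L) %/% nv + 1L
  del_v <- integer(n); del_j <- integer(n)
  for (v in unique(vi)) {
    k <- vi == v
    del_v[k] <- sample.int(params$d_max + 1L, sum(k), replace = TRUE,
                           prob = params$p_delv[v, ]) - 1L
  }
  for (j in unique(ji)) {
    k <- ji == j
    del_j[k] <- sample.int(params$d_max + 1L, sum(k), replace = TRUE,
                           prob = params$p_delj[j, ]) - 1L
  }
  ilen <- sample.int(params$i_max + 1L, n, replace = TRUE,
                     prob = params$p_ins) - 1L
  ins <- character(n); ins[] <- ""
  mx <- max(ilen)
  if (mx > 0) {
    cur <- integer(n)
    active <- ilen >= 1L
    cur[active] <- sample.int(4L, sum(active), replace = TRUE,
                              prob = params$ins_init)
    cols <- vector("list", mx)
    col <- character(n); col[active] <- .BASES[cur[active]]
    cols[[1]] <- col
    if (mx > 1) for (t in 2:mx) {
      active <- ilen >= t
      if (!any(active)) { cols[[t]] <- character(n); next }
      for (b in 1:4) {
        k <- active & cur == b
        if (any(k)) cur[k] <- sample.int(4L, sum(k), replace = TRUE,
                                         prob = params$ins_trans[b, ])
      }
      col <- character(n); col[] <- ""
      col[active] <- .BASES[cur[active]]
      cols[[t]] <- col
    }
    ins <- do.call(paste0, cols)
  }
  data.frame(v_name = germline$v$name[vi], j_name = germline$j$name[ji],
             del_v = del_v, del_j = del_j, ins_seq = ins,
             stringsAsFactors = FALSE)
}

# Realize scenarios and annotate frame class and CDR3 (anchor-to-anchor).
annotate_product <- function(sc, germline) {
  vi <- match(sc$v_name, germline$v$name)
  ji <- match(sc$j_name, germline$j$name)
  lv <- nchar(germline$v$seq)[vi]; av <- germline$v$anchor[vi]
  lj <- nchar(germline$j$seq)[ji]; aj <- germline$j$anchor[ji]
  bad_v <- sc$del_v > lv - av - 3L
  bad_j <- sc$del_j > aj
  if (any(bad_v | bad_j))
    stopf("%d scenarios delete a conserved anchor codon", sum(bad_v | bad_j))
  ilen <- nchar(sc$ins_seq)
  seq <- paste0(substring(germline$v$seq[vi], 1, lv - sc$del_v),
                sc$ins_seq,
                substring(germline$j$seq[ji], sc$del_j + 1, lj))
  span <- (lv - sc$del_v - av) + ilen + (aj - sc$del_j) + 3L
  n <- nchar(seq)
  cdr3_nt <- substring(seq, av + 1, av + span)
  frame_class <- ifelse(span %% 3L != 0L, "out_of_frame", NA)
  inf <- is.na(frame_class)
  if (any(inf)) {
    tail_len <- (n[inf] - av[inf]) %/% 3L * 3L
    aa_full <- translate_nt(substring(seq[inf], av[inf] + 1,
                                      av[inf] + tail_len))
    frame_class[inf] <- ifelse(has_stop(aa_full), "stop", "in_frame_productive")
  }
  cdr3_aa <- translate_nt(cdr3_nt)
  sc$seq <- seq
  sc$frame_class <- frame_class
  sc$cdr3_nt <- cdr3_nt
  sc$cdr3_aa <- cdr3_aa
  sc$L <- span %/% 3L
  sc
}

#' Simulate annotated reads from a fitted generation model
#'
#' @param object A `generation_model`.
#' @param nsim Number of reads to draw.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame of scenarios with realized sequences, frame class and
#'   CDR3 annotation.
#' @export
simulate.generation_model <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    sc <- draw_scenarios(object$params, object$germline, nsim)
    annotate_product(sc, object$germline)
  })
}

#' Simulate a read pool (out-of-frame, productive, or Q-selected)
#'
#' Runs the generative process forwards and filters to the requested frame
#' class. When `selection` is supplied, productive draws are additionally
#' thinned by acceptance-rejection with probability proportional to their
#' selection factor Q (capped at 1.2 times the maximum Q observed in the
#' first proposal batch), so the accepted pool follows
#' P_post = Q P_pre / E[Q].
#'
#' @param n Number of reads to return.
#' @param params A `generation_params` object.
#' @param germline A `germline_set`.
#' @param frame One of `"out_of_frame"`, `"productive"`, `"any"`.
#' @param selection `NULL`, or a function mapping the annotated draw data
#'   frame to non-negative selection factors Q (e.g. [aa_factor_selection()]).
#' @param q_cap Optional exact upper bound on Q (for enumerable feature
#'   spaces); when `NULL` the cap is estimated as 1.2 times the maximum Q of
#'   the first proposal batch.
#' @param seed Optional integer seed; identical seeds give identical pools.
#' @param max_draws Safety cap on total proposals.
#' @return Data frame of `n` annotated reads with truth columns (`id`, `seq`,
#'   scenario fields, `frame_class`, CDR3 fields).
#' @export
simulate_pool <- function(n, params, germline,
                          frame = c("out_of_frame", "productive", "any"),
                          selection = NULL, q_cap = NULL, seed = NULL,
                          max_draws = max(1000 * n, 200000)) {
  frame <- match.arg(frame)
  with_seed(seed, {
    out <- list(); got <- 0L; drawn <- 0L; cap <- q_cap
    accepted <- 0L; proposed <- 0L
    while (got < n) {
      rate <- if (drawn > 0 && got > 0) got / drawn else 1 / 3.5
      batch <- min(max(5000L, ceiling((n - got) / rate * 1.1)), 2000000L)
      if (drawn + batch > max_draws)
        stopf("simulate_pool exceeded max_draws = %d", max_draws)
      sc <- annotate_product(draw_scenarios(params, germline, batch), germline)
      drawn <- drawn + batch
      keep <- switch(frame,
                     out_of_frame = sc$frame_class == "out_of_frame",
                     productive = sc$frame_class == "in_frame_productive",
                     any = rep(TRUE, nrow(sc)))
      sc <- sc[keep, , drop = FALSE]
      if (!is.null(selection) && nrow(sc) > 0) {
        q <- selection(sc)
        if (any(q < 0) || any(!is.finite(q))) stopf("selection returned invalid Q")
        if (is.null(cap)) cap <- max(q) * 1.2
        proposed <- proposed + nrow(sc)
        acc <- stats::runif(nrow(sc)) < pmin(q / cap, 1)
        sc <- sc[acc, , drop = FALSE]
        accepted <- accepted + nrow(sc)
        if (proposed >= 500 && accepted / proposed < 1e-3)
          stopf("selection acceptance rate %.2g is below 1e-3 (Q too peaked)",
                accepted / proposed)
      }
      if (nrow(sc) > 0) { out[[length(out) + 1L]] <- sc; got <- got + nrow(sc) }
    }
    res <- do.call(rbind, out)[seq_len(n), , drop = FALSE]
    res$id <- sprintf("read%06d", seq_len(n))
    rownames(res) <- NULL
    res[, c("id", setdiff(names(res), "id"))]
  })
}

#' Per-amino-acid multiplicative selection
#'
#' Builds a selection function Q(sequence) = prod over CDR3 positions of
#' `factors[a_i]` for use as the `selection` argument of [simulate_pool()].
#' Amino acids absent from `factors` get factor 1.
#'
#' @param factors Named numeric vector, e.g. `c(G = 2, P = 0.5)`.
#' @return Function from an annotated draw data frame to Q values.
#' @export
aa_factor_selection <- function(factors) {
  function(sc) {
    L <- nchar(sc$cdr3_aa)
    lf <- log(factors)
    sym <- strsplit(paste(sc$cdr3_aa, collapse = ""), "")[[1]]
    contrib <- lf[sym]
    contrib[is.na(contrib)] <- 0
    out <- numeric(length(L))
    s <- rowsum(contrib, rep(seq_along(L), L), reorder = TRUE)
    out[as.integer(rownames(s))] <- s[, 1]
    exp(out)
  }
}

#' Gaussian stabilizing selection on CDR3 length
#'
#' Acceptance factor exp(-(L - centre)^2 / (2 width^2)): selection against
#' both short and long CDR3s, the stabilizing-selection scenario.
#'
#' @param centre Favoured CDR3 length (amino acids).
#' @param width Gaussian width (amino acids).
#' @return Function usable as the `selection` argument of [simulate_pool()].
#' @export
length_gaussian_selection <- function(centre, width) {
  function(sc) exp(-(sc$L - centre)^2 / (2 * width^2))
}

#' Simulate clonal families
#'
#' Founders are drawn from the generative process; descendants are copies of
#' their founder with `k` point substitutions at uniform positions (no
#' indels, so all members share the founder's V, J and junction length).
#' The first member of every family is the unmutated founder.
#'
#' @param n_families Number of families.
#' @param params,germline Generative model.
#' @param family_size_probs Probability vector over family sizes 1..K.
#' @param mutation_count_probs Probability vector over 0..M substitutions per
#'   descendant.
#' @param min_junction_dist If > 0, founders sharing a (V, J, junction
#'   length) key with an earlier family are redrawn until their junctions
#'   differ by at least this many nucleotides.
#' @param frame Frame filter applied to founders (default `"any"`).
#' @param seed Optional integer seed.
#' @return Data frame of reads with truth columns `family` and `n_mutations`.
#' @export
simulate_clonal_families <- function(n_families, params, germline,
                                     family_size_probs = c(2, 2, 2, 1, 1, 1, 1, 0.5, 0.3, 0.2),
                                     mutation_count_probs = c(0.5, 0.25, 0.15, 0.1),
                                     min_junction_dist = 0,
                                     frame = "any", seed = NULL) {
  family_size_probs <- family_size_probs / sum(family_size_probs)
  mutation_count_probs <- mutation_count_probs / sum(mutation_count_probs)
  with_seed(seed, {
    founders <- simulate_pool(n_families, params, germline, frame = frame)
    if (min_junction_dist > 0) {
      key <- paste(founders$v_name, founders$j_name, nchar(founders$ins_seq))
      for (i in seq_len(n_families)) {
        tries <- 0
        repeat {
          prev <- which(key[seq_len(i - 1)] == key[i])
          ok <- all(hamming_dist(founders$ins_seq[i],
                                 founders$ins_seq[prev]) >= min_junction_dist)
          if (ok) break
          tries <- tries + 1
          if (tries > 2000)
            stopf("cannot separate family junctions by %d nt", min_junction_dist)
          repl <- simulate_pool(1, params, germline, frame = frame)
          founders[i, names(repl)] <- repl
          key[i] <- paste(founders$v_name[i], founders$j_name[i],
                          nchar(founders$ins_seq[i]))
        }
      }
    }
    sizes <- sample.int(length(family_size_probs), n_families, replace = TRUE,
                        prob = family_size_probs)
    rows <- list()
    for (f in seq_len(n_families)) {
      fam <- founders[f, , drop = FALSE]
      members <- fam[rep(1, sizes[f]), , drop = FALSE]
      members$n_mutations <- 0L
      if (sizes[f] > 1) {
        for (m in 2:sizes[f]) {
          k <- sample.int(length(mutation_count_probs), 1,
                          prob = mutation_count_probs) - 1L
          if (k > 0) {
            s <- strsplit(members$seq[m], "")[[1]]
            pos <- sample.int(length(s), k)
            for (p in pos) s[p] <- sample(setdiff(.BASES, s[p]), 1)
            members$seq[m] <- paste(s, collapse = "")
          }
          members$n_mutations[m] <- k
        }
      }
      members$family <- sprintf("F%04d", f)
      members$id <- sprintf("F%04d_M%02d", f, seq_len(sizes[f]) - 1L)
      rows[[f]] <- members
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    res[, c("id", "family", "n_mutations",
            setdiff(names(res), c("id", "family", "n_mutations")))]
  })
}

#' Sample the pre-selection productive repertoire
#'
#' Monte-Carlo draws from the generative process restricted to productive
#' (in-frame, stop-free) realizations, returning the CDR3 feature tuples the
#' selection model is defined on.
#'
#' @param params A `generation_params` or fitted `generation_model`.
#' @param germline A `germline_set` (taken from the model when omitted).
#' @param n Number of productive draws.
#' @param seed Optional integer seed.
#' @return Data frame with columns `v_name`, `j_name`, `L`, `cdr3_aa`,
#'   `cdr3_nt`.
#' @export
sample_pre_repertoire <- function(params, germline = NULL, n, seed = NULL) {
  if (inherits(params, "generation_model")) {
    germline <- germline %||% params$germline
    params <- params$params
  }
  if (is.null(germline)) stopf("germline required")
  pool <- simulate_pool(n, params, germline, frame = "productive", seed = seed)
  pool[, c("v_name", "j_name", "L", "cdr3_aa", "cdr3_nt")]
}
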