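# Shared fixtures: the packaged toy germline, its reference parameters, and
# small builders used across test files.

toy_germline <- local({
  g <- NULL
  function() {
    if (is.null(g))
      g <<- load_germline(system.file("extdata", "toy_germline.fasta",
                                      package = "igkselect"))
    g
  }
})

toy_params <- function(...) toy_generation_params(toy_germline(), ...)

# Single-V single-J germline for fully enumerable models.
tiny_germline <- function() {
  g <- toy_germline()
  g$v <- g$v[1, , drop = FALSE]
  g$j <- g$j[1, , drop = FALSE]
  g
}

write_fasta_tmp <- function(ids, seqs, headers = ids) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", headers, "\n", seqs), path)
  path
}

# Truncate reference parameters to small d_max/i_max (renormalized).
shrink_params <- function(params, d_max, i_max) {
  cut <- function(m, k) {
    m <- m[, seq_len(k + 1), drop = FALSE]
    m / rowSums(m)
  }
  generation_params(params$p_vj, cut(params$p_delv, d_max),
                    cut(params$p_delj, d_max),
                    params$p_ins[seq_len(i_max + 1)] /
                      sum(params$p_ins[seq_len(i_max + 1)]),
                    params$ins_init, params$ins_trans)
}

# Manual selection model with given factor arrays (for oracle tests).
manual_selection_model <- function(vnames, jnames, L_max, q_vj, q_len, q_pos,
                                   z = 1) {
  structure(list(q_vj = q_vj, q_len = q_len, q_pos = q_pos, z = z,
                 L_max = L_max, granularity = "amino_acid",
                 genes = list(v = vnames, j = jnames),
                 diagnostics = list(min_count = 0)),
            class = "selection_model")
}

total_variation <- function(a, b) 0.5 * sum(abs(a - b))

# TV between joint (gene, deletion-count) tables given gene usage weights.
tv_joint_del <- function(p_del_a, usage_a, p_del_b, usage_b) {
  total_variation(as.vector(p_del_a * usage_a), as.vector(p_del_b * usage_b))
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
         a, b, USE.NAMES = FALSE)
}
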