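# JSON serialization of fitted models (versioned schemas) and TSV export of
# heatmap tables.

#' Write a generation model to JSON
#'
#' @param model A `generation_model` or `generation_params` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_generation_model <- function(model, path) {
  params <- if (inherits(model, "generation_model")) model$params else model
  doc <- list(
    schema = "igkselect/generation-model", version = 1L,
    d_max = params$d_max, i_max = params$i_max,
    v_names = rownames(params$p_vj), j_names = colnames(params$p_vj),
    p_vj = unname(as.matrix(params$p_vj)),
    p_delv = unname(as.matrix(params$p_delv)),
    p_delj = unname(as.matrix(params$p_delj)),
    p_ins = unname(params$p_ins),
    ins_init = unname(params$ins_init),
    ins_trans = unname(params$ins_trans))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a generation model from JSON
#'
#' @param path Path written by [write_generation_model()].
#' @return A `generation_params` object.
#' @export
read_generation_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "igkselect/generation-model"))
    stopf("%s is not a generation-model document", path)
  named <- function(m, rn, cn) { dimnames(m) <- list(rn, cn); m }
  generation_params(
    p_vj = named(doc$p_vj, doc$v_names, doc$j_names),
    p_delv = named(doc$p_delv, doc$v_names, 0:doc$d_max),
    p_delj = named(doc$p_delj, doc$j_names, 0:doc$d_max),
    p_ins = stats::setNames(doc$p_ins, 0:doc$i_max),
    ins_init = stats::setNames(doc$ins_init, .BASES),
    ins_trans = named(doc$ins_trans, .BASES, .BASES))
}

#' Write a selection model to JSON
#'
#' @param model A `selection_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_model <- function(model, path) {
  doc <- list(
    schema = "igkselect/selection-model", version = 1L,
    L_max = model$L_max, z = model$z, granularity = model$granularity,
    v_names = model$genes$v, j_names = model$genes$j,
    q_vj = unname(model$q_vj), q_len = unname(model$q_len),
    q_pos = as.vector(model$q_pos),
    q_codon = if (!is.null(model$q_codon)) as.vector(model$q_codon))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a selection model from JSON
#'
#' @param path Path written by [write_selection_model()].
#' @return A `selection_model` (without fitting diagnostics).
#' @export
read_selection_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "igkselect/selection-model"))
    stopf("%s is not a selection-model document", path)
  L <- doc$L_max
  model <- list(
    q_vj = matrix(unlist(doc$q_vj), length(doc$v_names), length(doc$j_names),
                  dimnames = list(doc$v_names, doc$j_names)),
    q_len = stats::setNames(as.numeric(doc$q_len), seq_len(L)),
    q_pos = array(as.numeric(doc$q_pos), c(L, L, 20L),
                  dimnames = list(pos = seq_len(L), len = seq_len(L), aa = .AA20)),
    z = doc$z, L_max = L, granularity = doc$granularity,
    genes = list(v = doc$v_names, j = doc$j_names),
    diagnostics = list(min_count = NA))
  if (!is.null(doc$q_codon) && length(doc$q_codon) > 0)
    model$q_codon <- array(as.numeric(doc$q_codon), c(L, L, 64L),
                           dimnames = list(pos = seq_len(L), len = seq_len(L),
                                           codon = names(.GENETIC_CODE)))
  class(model) <- "selection_model"
  model
}

#' Export a length-averaged heatmap table as TSV
#'
#' Symbol rows, position columns, `NA` rendered blank (no selection /
#' undefined).
#'
#' @param model A fitted `selection_model`.
#' @param path Output path.
#' @param granularity `"amino_acid"` or `"codon"`.
#' @return `path`, invisibly.
#' @export
write_heatmap_tsv <- function(model, path, granularity = "amino_acid") {
  tab <- average_log_q(model, granularity)
  if (is.list(tab)) tab <- tab$codon
  df <- data.frame(symbol = rownames(tab), tab, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
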