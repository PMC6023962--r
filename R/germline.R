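#' Load a germline V/J segment set
#'
#' Reads a FASTA file of germline V and J nucleotide segments whose headers
#' carry `kind=`, `anchor=` and `frame=` key-value tokens, e.g.
#' `>IGKV1 kind=V anchor=51 frame=0`. The anchor is the 0-based index of the
#' first nucleotide of the conserved codon bounding the CDR3: the cysteine
#' codon (TGT/TGC) near the 3' end of a V segment, and the phenylalanine
#' (TTT/TTC) or tryptophan (TGG) codon within a J segment. `frame` is the
#' reading-frame phase of position 0 (the anchor must sit in that frame).
#'
#' @param path Path to the germline FASTA file.
#' @return An object of class `germline_set`: a list with data frames `v` and
#'   `j`, each with columns `name`, `seq`, `anchor`, `frame`, ordered as in
#'   the file.
#' @examples
#' g <- load_germline(system.file("extdata", "toy_germline.fasta",
#'                                package = "igkselect"))
#' g
#' @export
load_germline <- function(path) {
  if (!file.exists(path)) stopf("germline file not found: %s", path)
  fa <- Biostrings::readDNAStringSet(path)
  headers <- names(fa)
  seqs <- as.character(fa)
  recs <- lapply(seq_along(fa), function(i) {
    toks <- strsplit(trimws(headers[i]), "\\s+")[[1]]
    name <- toks[1]
    kv <- toks[-1][grepl("=", toks[-1], fixed = TRUE)]
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- sub("=.*$", "", kv)
    for (tok in c("kind", "anchor", "frame")) {
      if (!tok %in% names(vals))
        stopf("germline record '%s' is missing the '%s=' header token", name, tok)
    }
    seq <- toupper(seqs[i])
    if (grepl("[^ACGT]", seq))
      stopf("germline record '%s' contains non-ACGT characters", name)
    anchor <- suppressWarnings(as.integer(vals[["anchor"]]))
    frame <- suppressWarnings(as.integer(vals[["frame"]]))
    kind <- vals[["kind"]]
    if (is.na(anchor) || anchor < 0 || anchor + 3 > nchar(seq))
      stopf("germline record '%s': anchor %s out of range for length %d",
            name, vals[["anchor"]], nchar(seq))
    if (is.na(frame) || frame < 0 || frame > 2)
      stopf("germline record '%s': frame must be 0, 1 or 2", name)
    if (!kind %in% c("V", "J"))
      stopf("germline record '%s': kind must be V or J", name)
    if ((anchor - frame) %% 3 != 0)
      stopf("germline record '%s': anchor %d is not in frame %d", name, anchor, frame)
    anchor_codon <- substr(seq, anchor + 1, anchor + 3)
    if (kind == "V" && !anchor_codon %in% c("TGT", "TGC"))
      stopf("germline record '%s': V anchor codon %s is not a cysteine codon",
            name, anchor_codon)
    if (kind == "J" && !anchor_codon %in% c("TTT", "TTC", "TGG"))
      stopf("germline record '%s': J anchor codon %s is not Phe/Trp", name, anchor_codon)
    data.frame(name = name, kind = kind, seq = seq, anchor = anchor,
               frame = frame, stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (anyDuplicated(recs$name[recs$kind == "V"]) ||
      anyDuplicated(recs$name[recs$kind == "J"]))
    stopf("duplicate germline segment names within a kind")
  out <- list(v = recs[recs$kind == "V", c("name", "seq", "anchor", "frame")],
              j = recs[recs$kind == "J", c("name", "seq", "anchor", "frame")])
  rownames(out$v) <- NULL
  rownames(out$j) <- NULL
  if (nrow(out$v) == 0 || nrow(out$j) == 0)
    stopf("germline set must contain at least one V and one J segment")
  class(out) <- "germline_set"
  out
}

#' @export
print.germline_set <- function(x, ...) {
  cat(sprintf("Germline set: %d V, %d J segments\n", nrow(x$v), nrow(x$j)))
  cat("V:", paste(x$v$name, collapse = ", "), "\n")
  cat("J:", paste(x$j$name, collapse = ", "), "\n")
  invisible(x)
}

#' Read a repertoire FASTA (with optional truth sidecar)
#'
#' @param path FASTA file of rearranged nucleotide reads.
#' @param sidecar Optional TSV of simulation truth keyed by `read_id`.
#' @param ambiguous How to treat reads containing characters outside A/C/G/T:
#'   `"error"` (default) or `"drop"` (silently removed).
#' @return A data frame with columns `id`, `seq` (file order), plus any
#'   sidecar columns joined by read id.
#' @export
read_repertoire <- function(path, sidecar = NULL, ambiguous = c("error", "drop")) {
  ambiguous <- match.arg(ambiguous)
  fa <- Biostrings::readDNAStringSet(path)
  ids <- unname(vapply(strsplit(names(fa), "\\s+"), `[`, character(1), 1L))
  if (anyDuplicated(ids))
    stopf("duplicate read id in %s: %s", path, ids[duplicated(ids)][1])
  seqs <- unname(toupper(as.character(fa)))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    if (ambiguous == "error")
      stopf("read '%s' contains ambiguous nucleotides (use ambiguous = \"drop\")",
            ids[bad][1])
    ids <- ids[!bad]; seqs <- seqs[!bad]
  }
  if (any(nchar(seqs) == 0)) stopf("empty sequence in %s", path)
  out <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  if (!is.null(sidecar)) {
    tr <- utils::read.delim(sidecar, stringsAsFactors = FALSE)
    if (!"read_id" %in% names(tr)) stopf("sidecar lacks a read_id column")
    unknown <- setdiff(tr$read_id, out$id)
    if (length(unknown) > 0) {
      warnf("%d sidecar rows have no matching read and were skipped", length(unknown))
      tr <- tr[tr$read_id %in% out$id, , drop = FALSE]
    }
    idx <- match(out$id, tr$read_id)
    for (cn in setdiff(names(tr), "read_id")) out[[cn]] <- tr[[cn]][idx]
  }
  out
}

#' Write a repertoire to FASTA (one line per sequence)
#'
#' @param reads Data frame with `id` and `seq` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  writeLines(paste0(">", reads$id, "\n", reads$seq), path, sep = "\n")
  invisible(path)
}

#' Write a simulation truth sidecar TSV
#'
#' @param reads Simulated reads with truth columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(reads, path) {
  cols <- intersect(c("id", "v_name", "j_name", "del_v", "del_j", "ins_seq",
                      "frame_class", "productive", "family", "n_mutations"),
                    names(reads))
  tr <- reads[, cols, drop = FALSE]
  names(tr)[names(tr) == "id"] <- "read_id"
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
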