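# Internal helpers shared across modules: genetic code, residue masses,
# fast string utilities and seed plumbing.

.BASES <- c("A", "C", "G", "T")

# Standard genetic code, indexed by codon string.
.GENETIC_CODE <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"
  ), "")[[1]]
  names(aa) <- codons
  aa
})

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Average residue masses (Da); a peptide weighs sum(residues) + one water.
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.01524

# Translate nucleotide strings (complete codons only; '*' marks stops).
# Vectorized by length group: a handful of substring passes per distinct
# sequence length instead of per-sequence splitting.
translate_nt <- function(seqs) {
  out <- character(length(seqs))
  ns <- nchar(seqs)
  for (n in unique(ns)) {
    k <- n %/% 3L
    idx <- which(ns == n)
    if (k == 0L) { out[idx] <- ""; next }
    aa <- vector("list", k)
    for (c_i in seq_len(k)) {
      aa[[c_i]] <- .GENETIC_CODE[substring(seqs[idx], 3L * c_i - 2L, 3L * c_i)]
    }
    out[idx] <- do.call(paste0, aa)
  }
  out
}

# Split sequences into codon strings; list output.
split_codons <- function(seqs) {
  lapply(seqs, function(s) {
    k <- nchar(s) %/% 3L
    if (k == 0L) return(character(0))
    substring(s, seq(1L, by = 3L, length.out = k), seq(3L, by = 3L, length.out = k))
  })
}

has_stop <- function(aa) grepl("*", aa, fixed = TRUE)

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage substream of a master seed (kept below 2^31).
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Count of mismatching characters between equal-length strings (vectorized).
hamming_dist <- function(a, b) {
  if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}
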