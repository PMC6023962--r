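# Deterministic clone detection: ungapped terminal V/J assignment, grouping
# by (V, J, junction length), germline-template alignment, neighbor-joining
# trees, and partition at a fixed mutation cutoff.

#' Assign V and J germline genes to reads
#'
#' Best-scoring ungapped terminal alignments: every V is scored as a read
#' prefix over candidate 3'-truncations and every J as a read suffix over
#' candidate 5'-truncations (score = matches - mismatches). The V/J boundary
#' pair is chosen jointly so the junction is non-negative. Ties break by
#' germline file order (genes) and by longer aligned stubs (boundaries).
#'
#' @param reads Data frame with `id` and `seq`, or character vector.
#' @param germline A `germline_set`.
#' @param d_max Maximum terminal truncation considered per side.
#' @param score_min Reads whose best V or J score falls below this are
#'   flagged unassigned.
#' @param min_len Minimum read length (shorter reads are unassigned).
#' @return Data frame with `read_id`, `v_name`, `j_name`, `v_end` (0-based
#'   exclusive end of the V match), `j_start` (0-based start of the J match),
#'   `vj_distance = j_start - v_end`, `score_v`, `score_j`, `assigned`.
#' @export
assign_vj <- function(reads, germline, d_max = 12, score_min = 15,
                      min_len = 30) {
  if (!is.data.frame(reads))
    reads <- data.frame(id = paste0("read", seq_along(reads)), seq = reads,
                        stringsAsFactors = FALSE)
  seqs <- reads$seq
  n <- length(seqs)
  ns <- nchar(seqs)

  score_side <- function(segments, side) {
    mdel <- if (side == "V") max_del_v(germline, d_max) else
      max_del_j(germline, d_max)
    best_score <- matrix(-Inf, n, nrow(segments))
    best_stub <- matrix(0L, n, nrow(segments))
    cand_scores <- vector("list", nrow(segments))
    cand_stubs <- vector("list", nrow(segments))
    for (g in seq_len(nrow(segments))) {
      gs <- segments$seq[g]; lg <- nchar(gs)
      stubs <- (lg - mdel[g]):lg          # aligned stub lengths
      sc <- matrix(-Inf, n, length(stubs))
      # per-position mismatch indicators, then cumulative over stub lengths
      mism <- matrix(0L, n, lg)
      for (p in seq_len(lg)) {
        if (side == "V") {
          rp <- substring(seqs, p, p)
          gp <- substr(gs, p, p)
        } else {
          # position p counted from the 3' end of both read and gene
          rp <- substring(seqs, ns - p + 1, ns - p + 1)
          gp <- substr(gs, lg - p + 1, lg - p + 1)
        }
        mism[, p] <- (rp != gp) + (rp == "") # off-read counts as mismatch
      }
      cum <- t(apply(mism, 1, cumsum))
      for (k in seq_along(stubs)) {
        st <- stubs[k]
        ok <- ns >= st
        sc[ok, k] <- st - 2 * cum[ok, st]
      }
      cand_scores[[g]] <- sc
      cand_stubs[[g]] <- stubs
      best_score[, g] <- apply(sc, 1, max)
      best_stub[, g] <- stubs[max.col(sc, ties.method = "last")]
    }
    list(best_score = best_score, best_stub = best_stub,
         cand_scores = cand_scores, cand_stubs = cand_stubs)
  }

  V <- score_side(germline$v, "V")
  J <- score_side(germline$j, "J")
  vg <- max.col(V$best_score, ties.method = "first")
  jg <- max.col(J$best_score, ties.method = "first")

  v_end <- integer(n); j_start <- integer(n)
  score_v <- numeric(n); score_j <- numeric(n)
  for (i in seq_len(n)) {
    sv <- V$cand_scores[[vg[i]]][i, ]
    sj <- J$cand_scores[[jg[i]]][i, ]
    ev <- V$cand_stubs[[vg[i]]]
    sjst <- ns[i] - J$cand_stubs[[jg[i]]]        # 0-based J starts
    tot <- outer(sv, sj, `+`)
    feas <- outer(ev, sjst, `<=`)
    tot[!feas] <- -Inf
    if (all(!is.finite(tot))) { score_v[i] <- -Inf; next }
    bm <- which(tot == max(tot), arr.ind = TRUE)
    # ties: longest V stub, then longest J stub
    bm <- bm[order(-bm[, 1], bm[, 2]), , drop = FALSE]
    v_end[i] <- ev[bm[1, 1]]
    j_start[i] <- sjst[bm[1, 2]]
    score_v[i] <- sv[bm[1, 1]]
    score_j[i] <- sj[bm[1, 2]]
  }
  assigned <- ns >= min_len & score_v >= score_min & score_j >= score_min
  out <- data.frame(
    read_id = reads$id,
    v_name = ifelse(assigned, germline$v$name[vg], NA_character_),
    j_name = ifelse(assigned, germline$j$name[jg], NA_character_),
    v_end = ifelse(assigned, v_end, NA_integer_),
    j_start = ifelse(assigned, j_start, NA_integer_),
    vj_distance = ifelse(assigned, j_start - v_end, NA_integer_),
    score_v = score_v, score_j = score_j, assigned = assigned,
    stringsAsFactors = FALSE)
  n_un <- sum(!assigned)
  if (n_un > 0) message(sprintf("%d/%d reads unassigned", n_un, n))
  out
}

#' Group assigned reads and align each group to a germline template
#'
#' Reads are grouped by V gene, J gene and junction extent, then aligned
#' columnwise against an artificial template of germline V, junction gap
#' characters and germline J. Two keying rules are available:
#' \describe{
#'   \item{`"length"` (default)}{key on (V, J, read length). Because somatic
#'     hypermutation introduces no indels, every clone member has the same
#'     read length, and unlike the per-read junction boundary call the
#'     length is immune to mutations at junction-adjacent bases. Rows align
#'     end to end (equal length by construction); the template uses the
#'     group's modal boundary call.}
#'   \item{`"junction"`}{key on (V, J, `vj_distance`) from the per-read
#'     boundary calls; rows are trimmed to the common germline window
#'     (same-length V and J segments).}
#' }
#'
#' @param assignments Output of [assign_vj()] (unassigned rows are dropped).
#' @param reads The reads data frame passed to [assign_vj()].
#' @param germline A `germline_set`.
#' @param by Grouping rule, `"length"` or `"junction"`.
#' @return Named list of groups; each holds `members` (read ids), `aligned`
#'   (equal-length sequences), `template`, `dist_germline` (mismatches to
#'   the template over non-gap columns), and the key fields.
#' @export
group_and_align <- function(assignments, reads, germline,
                            by = c("length", "junction")) {
  by <- match.arg(by)
  a <- assignments[assignments$assigned, , drop = FALSE]
  seqs <- reads$seq[match(a$read_id, reads$id)]
  ns <- nchar(seqs)
  keyval <- if (by == "junction") a$vj_distance else ns
  key <- paste(a$v_name, a$j_name, keyval, sep = "|")
  # deterministic group order: V order, J order, key value
  ord_key <- unique(key[order(match(a$v_name, germline$v$name),
                              match(a$j_name, germline$j$name),
                              keyval)])
  out <- list()
  for (k in ord_key) {
    idx <- which(key == k)
    vi <- match(a$v_name[idx][1], germline$v$name)
    ji <- match(a$j_name[idx][1], germline$j$name)
    lj <- nchar(germline$j$seq[ji])
    if (by == "junction") {
      vmin <- min(a$v_end[idx])
      jmin <- min(ns[idx] - a$j_start[idx])
      d <- a$vj_distance[idx][1]
      aligned <- paste0(substring(seqs[idx], 1, vmin),
                        substring(seqs[idx], a$v_end[idx] + 1, a$v_end[idx] + d),
                        substring(seqs[idx], ns[idx] - jmin + 1, ns[idx]))
    } else {
      # equal-length reads align end to end; boundary = modal call
      # (ties to the longer V stub)
      bnd <- table(paste(a$v_end[idx], a$j_start[idx]))
      bnd <- names(bnd)[order(-as.vector(bnd), -as.integer(sub(" .*", "", names(bnd))))][1]
      vmin <- as.integer(sub(" .*", "", bnd))
      jmin <- ns[idx][1] - as.integer(sub(".* ", "", bnd))
      d <- ns[idx][1] - vmin - jmin
      aligned <- seqs[idx]
    }
    template <- paste0(substr(germline$v$seq[vi], 1, vmin),
                       strrep("-", d),
                       substr(germline$j$seq[ji], lj - jmin + 1, lj))
    gseg <- paste0(substr(germline$v$seq[vi], 1, vmin),
                   substr(germline$j$seq[ji], lj - jmin + 1, lj))
    rseg <- paste0(substring(seqs[idx], 1, vmin),
                   substring(seqs[idx], ns[idx] - jmin + 1, ns[idx]))
    out[[k]] <- list(v_name = a$v_name[idx][1], j_name = a$j_name[idx][1],
                     vj_distance = d, members = a$read_id[idx],
                     aligned = aligned, template = template,
                     dist_germline = hamming_dist(gseg, rseg))
  }
  out
}

# Pairwise mismatch counts between equal-length aligned sequences.
pairwise_mismatch <- function(aligned) {
  m <- length(aligned)
  if (m == 1) return(matrix(0, 1, 1))
  M <- matrix(unlist(lapply(aligned, utf8ToInt)), nrow = m, byrow = TRUE)
  len <- ncol(M)
  matches <- matrix(0, m, m)
  for (b in unique(as.vector(M))) {
    I <- M == b
    matches <- matches + tcrossprod(I)
  }
  len - matches
}

#' Neighbor-joining tree from a mismatch matrix
#'
#' @param dist Symmetric matrix of pairwise mismatch counts (zero diagonal),
#'   with row names used as tip labels.
#' @return An `ape` `phylo` tree (a trivial one-edge tree for two taxa).
#' @export
nj_tree <- function(dist) {
  dist <- as.matrix(dist)
  m <- nrow(dist)
  if (is.null(rownames(dist))) rownames(dist) <- colnames(dist) <-
      paste0("t", seq_len(m))
  if (m < 2) stopf("need at least two taxa")
  if (m == 2) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(dist[1, 2] / 2, 2),
               tip.label = rownames(dist), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(stats::as.dist(dist))
}

#' Partition tree leaves into clones at a mutation cutoff
#'
#' Clones are the connected components of the leaf graph that links two
#' leaves when their distance is at most `cutoff`: tree-path (patristic)
#' distance by default, or raw pairwise mismatches (single linkage) with
#' `method = "hamming"`.
#'
#' @param tree A `phylo` tree (ignored for `method = "hamming"`).
#' @param cutoff Maximum linking distance (mutations); default 4.
#' @param method `"patristic"` (default) or `"hamming"`.
#' @param dist Raw mismatch matrix, required for `method = "hamming"`.
#' @return Integer vector of clone labels named by member.
#' @export
partition_clones <- function(tree, cutoff = 4, method = c("patristic", "hamming"),
                             dist = NULL) {
  method <- match.arg(method)
  if (method == "patristic") {
    D <- ape::cophenetic.phylo(tree)
    labels <- tree$tip.label
    D <- D[labels, labels, drop = FALSE]
  } else {
    if (is.null(dist)) stopf("method = \"hamming\" needs the dist matrix")
    D <- as.matrix(dist)
    labels <- rownames(D)
  }
  m <- nrow(D)
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  link <- D <= cutoff + 1e-9
  for (i in seq_len(m - 1)) for (j in (i + 1):m) if (link[i, j]) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comp <- match(roots, unique(roots))
  names(comp) <- labels
  comp
}

#' Choose the ancestor of a clone
#'
#' The member closest to the germline template (fewest mismatches over the
#' templated V and J columns); ties break to the lexicographically smallest
#' read id.
#'
#' @param members Read ids of the clone.
#' @param dist_germline Mismatch counts to the germline template, aligned
#'   with `members`.
#' @return The ancestor read id.
#' @export
clone_ancestor <- function(members, dist_germline) {
  stopifnot(length(members) == length(dist_germline), length(members) > 0)
  cand <- members[dist_germline == min(dist_germline)]
  sort(cand)[1]
}

#' Detect clones in a repertoire
#'
#' The full deterministic pipeline: V/J assignment, grouping by (V, J,
#' junction length), within-group alignment, a neighbor-joining tree per
#' group, partition at the mutation cutoff, and ancestor choice per clone.
#'
#' @param reads Data frame with `id`, `seq`.
#' @param germline A `germline_set`.
#' @param cutoff Mutation cutoff (default 4).
#' @param method Leaf-distance rule for the partition: `"patristic"`
#'   (default) or `"hamming"`.
#' @param group_by Group keying rule, see [group_and_align()].
#' @param ... Passed to [assign_vj()].
#' @return Data frame with one row per assigned read: `group_key`,
#'   `clone_id`, `read_id`, `is_ancestor`, `distance_to_germline`.
#' @export
detect_clones <- function(reads, germline, cutoff = 4,
                          method = c("patristic", "hamming"),
                          group_by = c("length", "junction"), ...) {
  method <- match.arg(method)
  group_by <- match.arg(group_by)
  assignments <- assign_vj(reads, germline, ...)
  groups <- group_and_align(assignments, reads, germline, by = group_by)
  rows <- list(); clone_counter <- 0L
  for (k in names(groups)) {
    g <- groups[[k]]
    m <- length(g$members)
    if (m == 1) {
      comp <- stats::setNames(1L, g$members)
    } else {
      D <- pairwise_mismatch(g$aligned)
      rownames(D) <- colnames(D) <- g$members
      if (method == "patristic") {
        comp <- partition_clones(nj_tree(D), cutoff, method = "patristic")
      } else {
        comp <- partition_clones(NULL, cutoff, method = "hamming", dist = D)
      }
      comp <- comp[g$members]
    }
    # deterministic clone order: by smallest member id within the group
    for (cl in unique(comp[order(names(comp))])) {
      clone_counter <- clone_counter + 1L
      mem <- names(comp)[comp == cl]
      dg <- g$dist_germline[match(mem, g$members)]
      anc <- clone_ancestor(mem, dg)
      ord <- order(mem)
      rows[[clone_counter]] <- data.frame(
        group_key = k, clone_id = sprintf("C%06d", clone_counter),
        read_id = mem[ord], is_ancestor = mem[ord] == anc,
        distance_to_germline = dg[ord], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
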