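# Repeat typing: global pairwise identity, single-linkage clustering at a
# strict identity threshold, heterogeneity flags, and a UPGMA tree over
# type representatives.

aa_substitution_matrix <- function(match = 1, mismatch = 0) {
  letters <- protein_letters()
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m
}

#' Global pairwise identity of two protein sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch 0, and a
#' linear gap penalty of -1 per gapped position; identity is the number of
#' matched positions divided by the alignment length (gaps included), so it
#' is symmetric and equals 1 only for identical sequences.
#'
#' @param a,b Non-empty protein strings.
#' @param match,mismatch,gap Alignment scores (defaults +1 / 0 / -1).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AAAA", "AAAAAA") # 4 matches / alignment length 6
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = aa_substitution_matrix(match, mismatch),
    gapOpening = 0, gapExtension = abs(gap))
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alen
}

#' All-against-all identity matrix
#'
#' @param seqs Character vector of protein sequences.
#' @return Symmetric numeric matrix of [pairwise_identity()] values with
#'   unit diagonal.
#' @export
identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(seqs[i], seqs[j])
      }
    }
  }
  m
}

# union-find over n items; returns component representative per item
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      ri <- find(pairs[k, 1]); rj <- find(pairs[k, 2])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster repeat modules into types by pairwise identity
#'
#' Single-linkage clustering: two modules share a type when they are
#' connected through pairs of strictly greater than `threshold` identity
#' (so a pair at exactly the threshold stays separate). Identical
#' sequences (identity 1) always share a type, whatever the threshold.
#' Types are numbered by first-member appearance, which makes the result
#' deterministic given input order.
#'
#' @param modules Tibble with a `seq` column (and ideally `module_id`,
#'   created when absent), e.g. from [scan_proteins()].
#' @param threshold Identity threshold; default 0.70.
#' @return The input tibble with a `type_id` column (`T01`, `T02`, ...);
#'   the identity matrix is attached as attribute `"identity"`.
#' @export
cluster_repeats <- function(modules, threshold = 0.70) {
  stopifnot(is.data.frame(modules), "seq" %in% names(modules),
            nrow(modules) >= 1)
  if (!"module_id" %in% names(modules)) {
    modules$module_id <- sprintf("module_%d", seq_len(nrow(modules)))
  }
  n <- nrow(modules)
  idm <- identity_matrix(modules$seq)
  pairs <- which(upper.tri(idm) & (idm > threshold | idm == 1),
                 arr.ind = TRUE)
  comp <- uf_components(n, pairs)
  first <- match(unique(comp), comp)      # order of first appearance
  type_no <- match(comp, comp[sort(first)])
  modules$type_id <- sprintf("T%02d", type_no)
  attr(modules, "identity") <- idm
  modules
}

#' Flag a repeat type as heterogeneous
#'
#' A type is het when its mean pairwise divergence (1 - identity) exceeds
#' `het_divergence`; solo types (no pairs) are never het.
#'
#' @param identities Numeric vector of within-type pairwise identities
#'   (empty for a solo type).
#' @param het_divergence Divergence threshold; default 0.05.
#' @return Logical.
#' @export
flag_het <- function(identities, het_divergence = 0.05) {
  if (length(identities) == 0) return(FALSE)
  mean(1 - identities) > het_divergence
}

#' Summarise repeat types
#'
#' One row per type: member count, solo flag, representative sequence
#' (longest member, first on ties), mean within-type pairwise identity
#' (`NA` for solo types), the het call ([flag_het()]), and a
#' `het_marginal` flag for types whose divergence falls in the open band
#' between the het threshold and the strongly heterogeneous regime.
#'
#' @param clustered Output of [cluster_repeats()].
#' @param config A [ddxp_config()] (supplies the het thresholds).
#' @return Tibble with columns `type_id`, `n_members`, `member_ids`
#'   (list), `representative`, `mean_identity`, `solo`, `het`,
#'   `het_marginal`.
#' @export
repeat_type_table <- function(clustered, config = ddxp_config()) {
  stopifnot(is.data.frame(clustered), "type_id" %in% names(clustered))
  idm <- attr(clustered, "identity")
  if (is.null(idm)) idm <- identity_matrix(clustered$seq)
  types <- sort(unique(clustered$type_id))
  rows <- map(types, function(tp) {
    idx <- which(clustered$type_id == tp)
    seqs <- clustered$seq[idx]
    rep_idx <- idx[order(-nchar(seqs))[1]]
    ids <- if (length(idx) > 1) idm[idx, idx][upper.tri(diag(length(idx)))]
           else numeric(0)
    div <- if (length(ids) > 0) mean(1 - ids) else NA_real_
    tibble(
      type_id = tp,
      n_members = length(idx),
      member_ids = list(clustered$module_id[idx]),
      representative = clustered$seq[rep_idx],
      mean_identity = if (length(ids) > 0) mean(ids) else NA_real_,
      solo = length(idx) == 1,
      het = flag_het(ids, config$het_divergence),
      het_marginal = !is.na(div) && div > config$het_divergence &&
        div <= config$het_marginal
    )
  })
  bind_rows(rows)
}

#' UPGMA tree over repeat-type representatives
#'
#' Distances are 1 - [pairwise_identity()] between representatives;
#' average-linkage (UPGMA) clustering yields an ultrametric tree which is
#' returned in Newick form with branch lengths.
#'
#' @param types Type table from [repeat_type_table()] (needs `type_id` and
#'   `representative`), with at least 2 rows.
#' @return Newick string.
#' @examples
#' tt <- tibble::tibble(type_id = c("A", "B"),
#'                      representative = c(strrep("AD", 10), strrep("VL", 10)))
#' upgma_tree(tt)
#' @export
upgma_tree <- function(types) {
  stopifnot(is.data.frame(types),
            all(c("type_id", "representative") %in% names(types)))
  if (nrow(types) < 2) abort("need at least 2 types to build a tree")
  d <- 1 - identity_matrix(types$representative)
  dimnames(d) <- list(types$type_id, types$type_id)
  upgma_newick(d)
}

#' UPGMA tree from a distance matrix, in Newick form
#'
#' Average-linkage agglomeration; leaf depths equal half the merge
#' heights, so the tree is ultrametric and the patristic distance between
#' two leaves reproduces their cophenetic distance.
#'
#' @param d Symmetric distance matrix with row/column names (>= 2 taxa).
#' @return Newick string with branch lengths.
#' @examples
#' d <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' upgma_newick(d)
#' @export
upgma_newick <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 2, !is.null(rownames(d)))
  hc <- hclust(as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy)
}
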