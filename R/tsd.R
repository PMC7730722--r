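# Target-site-duplication detection at module junctions of a coding
# sequence, and IUPAC consensus recovery from the detected copies.

#' Map a protein module span onto its coding sequence
#'
#' @param module_span Length-2 integer vector, the module's 0-based
#'   half-open protein interval.
#' @param pairing A [cds_pairing()].
#' @return Length-2 integer vector, the 0-based half-open CDS interval
#'   `[frame_offset + 3*start, frame_offset + 3*end)`.
#' @examples
#' map_module_to_cds(c(100, 280), cds_pairing("p", "c", 0))
#' @export
map_module_to_cds <- function(module_span, pairing) {
  stopifnot(length(module_span) == 2, inherits(pairing, "cds_pairing"))
  as.integer(pairing$frame_offset + 3L * module_span)
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Detect 18-bp target site duplications flanking module-encoding DNA
#'
#' The search is anchored at module junctions: for each module the 18 bp
#' closing its CDS interval are compared with the 18 bp closing the
#' preceding segment (the N region for the first module). A junction is
#' reported when the two copies differ at no more than
#' `config$max_tsd_mismatches` positions; both copies are additionally
#' scored against the 18-bp endonuclease recognition consensus (`TSD18`).
#' Modules whose interval starts fewer than 18 bp into the CDS are skipped
#' and listed in the `"skipped_modules"` attribute.
#'
#' @param cds CDS record tibble (one row) or DNA string.
#' @param arch A `ddxp_architecture` with at least one module.
#' @param pairing A [cds_pairing()]; validated against `cds` and the
#'   architecture's protein before use.
#' @param config A [ddxp_config()].
#' @return Tibble with one row per supported junction: `module_index`,
#'   `left_start`, `left_end`, `right_start`, `right_end` (0-based
#'   half-open CDS coordinates), `left_seq`, `right_seq`,
#'   `mismatches_between_copies`, `consensus_mismatches_left`,
#'   `consensus_mismatches_right`.
#' @export
detect_tsds <- function(cds, arch, pairing, config = ddxp_config()) {
  stopifnot(inherits(arch, "ddxp_architecture"))
  cseq <- toupper(if (is.data.frame(cds)) cds$seq[[1]] else cds)
  if (nrow(arch$modules) == 0) abort("architecture has no modules")
  validate_pairing(arch$seq, cseq, pairing)
  tsd18 <- tsd18_pattern()
  skipped <- integer(0)
  rows <- list()
  for (i in seq_len(nrow(arch$modules))) {
    span <- map_module_to_cds(c(arch$modules$start[i], arch$modules$end[i]),
                              pairing)
    if (span[1] < 18L) {
      skipped <- c(skipped, i)
      next
    }
    left <- c(span[1] - 18L, span[1])
    right <- c(span[2] - 18L, span[2])
    left_seq <- substr(cseq, left[1] + 1L, left[2])
    right_seq <- substr(cseq, right[1] + 1L, right[2])
    mm <- hamming(left_seq, right_seq)
    if (mm > config$max_tsd_mismatches) next
    rows[[length(rows) + 1L]] <- tibble(
      module_index = i,
      left_start = left[1], left_end = left[2],
      right_start = right[1], right_end = right[2],
      left_seq = left_seq, right_seq = right_seq,
      mismatches_between_copies = mm,
      consensus_mismatches_left = count_iupac_mismatches(left_seq, tsd18),
      consensus_mismatches_right = count_iupac_mismatches(right_seq, tsd18)
    )
  }
  out <- if (length(rows) > 0) bind_rows(rows) else tibble(
    module_index = integer(0), left_start = integer(0),
    left_end = integer(0), right_start = integer(0),
    right_end = integer(0), left_seq = character(0),
    right_seq = character(0), mismatches_between_copies = integer(0),
    consensus_mismatches_left = integer(0),
    consensus_mismatches_right = integer(0)
  )
  attr(out, "skipped_modules") <- skipped
  out
}

#' Derive the endonuclease recognition consensus from TSD evidence
#'
#' Pools all left and right duplication copies and builds the column-wise
#' minimal IUPAC consensus, i.e. the narrowest degenerate 18-mer every
#' observed copy matches.
#'
#' @param evidence Evidence tibble from [detect_tsds()] with at least 2
#'   rows.
#' @return A DNA [motif_pattern()] of length 18.
#' @export
consensus_from_tsds <- function(evidence) {
  stopifnot(is.data.frame(evidence))
  if (nrow(evidence) < 2) abort("need at least 2 TSD evidence entries")
  copies <- c(evidence$left_seq, evidence$right_seq)
  build_iupac_consensus(copies, id = "tsd_consensus")
}
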