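# FASTA input/output, bacterial-code translation, CDS/protein pairing, and
# GFF3 feature emission. Coordinates are 0-based half-open internally and
# converted to 1-based inclusive only when GFF3 lines are written.

the <- new.env(parent = emptyenv())

genetic_code_11 <- function() {
  if (is.null(the$gc11)) the$gc11 <- Biostrings::getGeneticCode("11")
  the$gc11
}

valid_chars <- function(alphabet) {
  if (alphabet == "protein") protein_letters() else dna_iupac_letters()
}

#' Read a multi-record FASTA file
#'
#' Residues are uppercased and validated against the declared alphabet
#' (protein: the 20 standard amino acids plus `X`; DNA: `ACGT` plus IUPAC
#' ambiguity codes).
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"protein"` or `"dna"`.
#' @return Tibble with one row per record, columns `id` (first header
#'   token), `description` (header remainder), `seq`, `alphabet`; input
#'   order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "ddgp"), fa)
#' read_fasta(fa, "protein")
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("FASTA parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  ok <- valid_chars(alphabet)
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0) {
      abort(sprintf("empty sequence for record '%s'", ids[i]))
    }
    chars <- strsplit(seqs[i], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad) > 0) {
      abort(sprintf(
        "illegal %s residue '%s' in record '%s' at position %d",
        alphabet, chars[bad[1]], ids[i], bad[1]))
    }
  }
  tibble(id = unname(ids), description = unname(desc),
         seq = unname(seqs), alphabet = alphabet)
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally
#'   `description` (appended to the header after a space).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description
          else rep("", nrow(records))
  headers <- ifelse(nchar(desc) > 0, paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Translate a coding sequence with the bacterial genetic code (table 11)
#'
#' One amino acid per complete codon after skipping `frame_offset` bases; a
#' trailing incomplete codon is dropped. Internal stops render as `*`;
#' codons containing non-`ACGT` characters render as `X`.
#'
#' @param dna DNA string.
#' @param frame_offset Number of bases skipped before codon 1 (>= 0).
#' @return Protein string.
#' @examples
#' translate_cds("GACGACGGCCCG")
#' @export
translate_cds <- function(dna, frame_offset = 0L) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (frame_offset < 0) abort("frame_offset must be >= 0")
  if (frame_offset >= n) abort("frame_offset is beyond the end of the sequence")
  if (n - frame_offset < 3) abort("fewer than one complete codon after frame_offset")
  gc <- genetic_code_11()
  starts <- seq.int(frame_offset + 1L, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Pair a protein with its coding sequence
#'
#' @param protein_id,cds_id Record identifiers.
#' @param frame_offset Bases skipped before codon 1 of the protein.
#' @return A list of class `cds_pairing`.
#' @seealso [validate_pairing()]
#' @export
cds_pairing <- function(protein_id, cds_id, frame_offset = 0L) {
  stopifnot(frame_offset >= 0)
  structure(list(protein_id = protein_id, cds_id = cds_id,
                 frame_offset = as.integer(frame_offset)),
            class = "cds_pairing")
}

#' Check that a CDS actually encodes a protein
#'
#' The CDS (from `frame_offset` on) must translate to the protein exactly,
#' excluding a trailing stop; internal stops are rejected. When a stop is
#' present the CDS length must satisfy
#' `len(cds) - frame_offset - 3 == 3 * len(protein)`.
#'
#' @param protein,cds One-row record tibbles (or plain strings).
#' @param pairing A [cds_pairing()].
#' @return `TRUE`, invisibly; otherwise an error describing the mismatch.
#' @export
validate_pairing <- function(protein, cds, pairing) {
  pseq <- if (is.data.frame(protein)) protein$seq[[1]] else toupper(protein)
  cseq <- if (is.data.frame(cds)) cds$seq[[1]] else toupper(cds)
  tr <- translate_cds(cseq, pairing$frame_offset)
  has_stop <- grepl("\\*$", tr)
  core <- sub("\\*$", "", tr)
  if (grepl("\\*", core)) {
    abort(sprintf("CDS '%s' has an internal stop codon", pairing$cds_id))
  }
  if (core != pseq) {
    abort(sprintf("CDS '%s' does not translate to protein '%s'",
                  pairing$cds_id, pairing$protein_id))
  }
  if (has_stop &&
      (nchar(cseq) - pairing$frame_offset - 3L) != 3L * nchar(pseq)) {
    abort(sprintf("CDS '%s' length inconsistent with protein '%s'",
                  pairing$cds_id, pairing$protein_id))
  }
  invisible(TRUE)
}

gff3_line <- function(seqid, type, start0, end0, attrs, score = ".",
                      strand = ".") {
  # internal 0-based half-open -> GFF3 1-based inclusive
  sprintf("%s\tddxpscan\t%s\t%d\t%d\t%s\t%s\t.\t%s",
          seqid, type, start0 + 1L, end0, score, strand, attrs)
}

#' Emit a protein architecture as GFF3 text
#'
#' One feature line per N region, module, C region, and annotated motif
#' hit; target-site-duplication evidence (CDS coordinates) is written when
#' `tsds` and `pairing` are given. Coordinates are converted to GFF3's
#' 1-based inclusive convention on output.
#'
#' @param arch A `ddxp_architecture` from [segment_modules()].
#' @param pairing Optional [cds_pairing()]; needed only for TSD features.
#' @param tsds Optional TSD evidence tibble from [detect_tsds()].
#' @param file Optional path; when given, lines are also written there.
#' @return Character vector of GFF3 lines, invisibly when `file` is given.
#' @export
write_features <- function(arch, pairing = NULL, tsds = NULL, file = NULL) {
  stopifnot(inherits(arch, "ddxp_architecture"))
  id <- arch$protein_id
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", id, arch$length))
  if (arch$n_region[2] > arch$n_region[1]) {
    lines <- c(lines, gff3_line(id, "polypeptide_region",
                                arch$n_region[1], arch$n_region[2],
                                sprintf("ID=%s.N;Name=N_region", id)))
  }
  mods <- arch$modules
  if (nrow(mods) > 0) {
    for (i in seq_len(nrow(mods))) {
      lines <- c(lines, gff3_line(
        id, "repeat_unit", mods$start[i], mods$end[i],
        sprintf("ID=%s.module%d;Name=module_%d;terminal_motif=%s;size_class=%s",
                id, i, i, mods$terminal_motif[i], mods$size_class[i])))
      lines <- c(lines, gff3_line(
        id, "polypeptide_motif", mods$end[i] - 4L, mods$end[i],
        sprintf("ID=%s.module%d.ddxp;Name=DDxP;Parent=%s.module%d",
                id, i, id, i)))
      dg <- mods$dgdgd_hits[[i]]
      if (!is.null(dg) && nrow(dg) > 0) {
        for (j in seq_len(nrow(dg))) {
          lines <- c(lines, gff3_line(
            id, "polypeptide_motif", dg$start[j], dg$end[j],
            sprintf("ID=%s.module%d.dgdgd%d;Name=DGDGD;Parent=%s.module%d",
                    id, i, j, id, i)))
        }
      }
    }
  }
  if (arch$c_region[2] > arch$c_region[1]) {
    lines <- c(lines, gff3_line(id, "polypeptide_region",
                                arch$c_region[1], arch$c_region[2],
                                sprintf("ID=%s.C;Name=C_region", id)))
  }
  if (!is.null(tsds) && nrow(tsds) > 0) {
    if (is.null(pairing)) abort("TSD features need a cds pairing")
    for (i in seq_len(nrow(tsds))) {
      lines <- c(lines, gff3_line(
        pairing$cds_id, "direct_repeat",
        tsds$left_start[i], tsds$left_end[i],
        sprintf("ID=%s.tsd%dL;Name=TSD;copy=left;module=%d",
                pairing$cds_id, i, tsds$module_index[i])))
      lines <- c(lines, gff3_line(
        pairing$cds_id, "direct_repeat",
        tsds$right_start[i], tsds$right_end[i],
        sprintf("ID=%s.tsd%dR;Name=TSD;copy=right;module=%d",
                pairing$cds_id, i, tsds$module_index[i])))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
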