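# Degenerate motif scanning on protein and DNA alphabets, plus IUPAC
# consensus construction. Internal coordinates are 0-based, half-open.

protein_letters <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X")
}

dna_iupac_letters <- function() names(Biostrings::IUPAC_CODE_MAP)

#' Expand an IUPAC nucleotide code to the plain bases it covers
#'
#' @param code A single IUPAC letter (case-insensitive; `"N"` covers all
#'   four bases).
#' @return Character vector of bases in `ACGT`.
#' @examples
#' iupac_expand("Y")
#' @export
iupac_expand <- function(code) {
  code <- toupper(code)
  exp <- Biostrings::IUPAC_CODE_MAP[[code]]
  if (is.null(exp)) abort(paste0("not an IUPAC code: ", code))
  strsplit(exp, "")[[1]]
}

# minimal IUPAC code covering a set of observed bases
iupac_code_for <- function(bases) {
  Biostrings::mergeIUPACLetters(paste(sort(unique(toupper(bases))), collapse = ""))
}

#' Construct a degenerate motif pattern
#'
#' A pattern is an ordered list of per-position residue sets. For protein
#' patterns each element is a string of allowed residues (`""` admits any
#' amino acid); for DNA patterns each element is one IUPAC code.
#'
#' @param id Pattern identifier.
#' @param alphabet `"protein"` or `"dna"`.
#' @param elements Character vector, one element per position.
#' @return A list of class `motif_pattern`.
#' @examples
#' motif_pattern("DDXP", "protein", c("D", "D", "", "P"))
#' @export
motif_pattern <- function(id, alphabet = c("protein", "dna"), elements) {
  alphabet <- match.arg(alphabet)
  elements <- toupper(as.character(elements))
  if (length(elements) < 1) abort("pattern must have length >= 1")
  if (alphabet == "dna") {
    bad <- !elements %in% dna_iupac_letters()
    if (any(bad)) {
      abort(paste0("pattern '", id, "': invalid IUPAC code(s): ",
                   paste(unique(elements[bad]), collapse = ", ")))
    }
  } else {
    for (el in elements) {
      if (nchar(el) == 0) next
      chars <- strsplit(el, "")[[1]]
      bad <- setdiff(chars, protein_letters())
      if (length(bad) > 0) {
        abort(paste0("pattern '", id, "': invalid residue(s): ",
                     paste(bad, collapse = ", ")))
      }
    }
  }
  structure(list(id = id, alphabet = alphabet, elements = elements),
            class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern %s (%s), length %d> %s\n",
              x$id, x$alphabet, length(x$elements), pattern_string(x)))
  invisible(x)
}

#' Display form of a motif pattern
#'
#' DNA patterns print as an IUPAC string; protein positions print as the
#' residue, a bracketed set, or `x` for "any".
#'
#' @param pattern A [motif_pattern()].
#' @return A single string.
#' @export
pattern_string <- function(pattern) {
  if (pattern$alphabet == "dna") return(paste(pattern$elements, collapse = ""))
  paste(vapply(pattern$elements, function(el) {
    if (nchar(el) == 0) "x" else if (nchar(el) == 1) el else paste0("[", el, "]")
  }, character(1)), collapse = "")
}

pattern_length <- function(pattern) length(pattern$elements)

# regex (one character class per position); used with a lookahead so that
# overlapping occurrences are all reported
pattern_regex <- function(pattern) {
  cls <- vapply(pattern$elements, function(el) {
    if (pattern$alphabet == "dna") {
      paste0("[", paste(iupac_expand(el), collapse = ""), "]")
    } else if (nchar(el) == 0) {
      "[A-Z]"
    } else if (nchar(el) == 1) {
      el
    } else {
      paste0("[", el, "]")
    }
  }, character(1))
  paste(cls, collapse = "")
}

#' Built-in motif patterns of the DDxP protein family
#'
#' * `DDXP`: terminal tetrapeptide Asp-Asp-x-Pro closing every repeat
#'   module (x unrestricted by default; see [ddxp_config()]).
#' * `DGDGD`: the exact Asp-Gly-Asp-Gly-Asp Asp-rich motif found a short,
#'   fixed distance upstream of the terminal motif.
#' * `RTX9`: the RTX nonapeptide consensus x-(L/I/F)-x-G-G-x-G-(N/D)-D used
#'   to separate group-I from group-II proteins.
#' * `TSD18`: the 18-bp endonuclease recognition consensus
#'   `DTYNNNGAYGAYGKNCCV` whose in-frame translation ends Asp-Asp-x-Pro.
#'
#' @param config A [ddxp_config()]; controls the wildcard set and relaxed
#'   mode of the `DDXP` pattern.
#' @return Named list of [motif_pattern()] objects.
#' @examples
#' motif_patterns()$TSD18
#' @export
motif_patterns <- function(config = ddxp_config()) {
  list(
    DDXP = ddxp_terminal_pattern(config),
    DGDGD = motif_pattern("DGDGD", "protein", c("D", "G", "D", "G", "D")),
    RTX9 = motif_pattern("RTX9", "protein",
                         c("", "LIF", "", "G", "G", "", "G", "ND", "D")),
    TSD18 = tsd18_pattern()
  )
}

ddxp_terminal_pattern <- function(config = ddxp_config()) {
  x <- if (is.null(config$x_allowed)) "" else paste(config$x_allowed, collapse = "")
  second <- if (isTRUE(config$relaxed_terminal)) "" else "D"
  motif_pattern("DDXP", "protein", c("D", second, x, "P"))
}

tsd18_pattern <- function() {
  motif_pattern("TSD18", "dna", strsplit("DTYNNNGAYGAYGKNCCV", "")[[1]])
}

#' Scan a sequence for all (possibly overlapping) motif occurrences
#'
#' @param seq A sequence string, or a one-row record tibble from
#'   [read_fasta()] (in which case the record's alphabet is used).
#' @param pattern A [motif_pattern()].
#' @param alphabet Alphabet of `seq` when given as a bare string; checked
#'   against the pattern's alphabet.
#' @return Tibble with columns `pattern_id`, `start`, `end` (0-based,
#'   half-open), `matched`; sorted by `start`. Overlapping hits are all
#'   reported.
#' @examples
#' scan_motif("AAADDGPAAA", motif_patterns()$DDXP, alphabet = "protein")
#' @export
scan_motif <- function(seq, pattern, alphabet = NULL) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    alphabet <- seq$alphabet[[1]]
    seq <- seq$seq[[1]]
  }
  if (!is.null(alphabet) && alphabet != pattern$alphabet) {
    abort(sprintf("alphabet mismatch: sequence is %s, pattern '%s' is %s",
                  alphabet, pattern$id, pattern$alphabet))
  }
  seq <- toupper(seq)
  k <- pattern_length(pattern)
  rx <- paste0("(?=", pattern_regex(pattern), ")")
  m <- gregexpr(rx, seq, perl = TRUE)[[1]]
  starts <- as.integer(m[m > 0]) - 1L
  tibble(
    pattern_id = rep(pattern$id, length(starts)),
    start = starts,
    end = starts + k,
    matched = if (length(starts) == 0) character(0) else
      substring(seq, starts + 1L, starts + k)
  )
}

#' Test an equal-length DNA string against an IUPAC pattern
#'
#' @param dna DNA string, same length as the pattern.
#' @param pattern A DNA [motif_pattern()].
#' @return `TRUE` iff every base lies in its position's IUPAC set.
#' @examples
#' iupac_match("TTCGCAGACGACGGCCCG", tsd18_pattern())
#' @export
iupac_match <- function(dna, pattern) {
  count_iupac_mismatches(dna, pattern) == 0L
}

#' Count positions of a DNA string violating an IUPAC pattern
#'
#' Zero mismatches is equivalent to [iupac_match()] being `TRUE`.
#'
#' @inheritParams iupac_match
#' @return Integer number of violating positions.
#' @export
count_iupac_mismatches <- function(dna, pattern) {
  if (pattern$alphabet != "dna") abort("pattern is not a DNA pattern")
  dna <- toupper(dna)
  if (nchar(dna) != pattern_length(pattern)) {
    abort(sprintf("length mismatch: sequence has %d bases, pattern '%s' has %d positions",
                  nchar(dna), pattern$id, pattern_length(pattern)))
  }
  bases <- strsplit(dna, "")[[1]]
  ok <- vapply(seq_along(bases), function(i) {
    bases[i] %in% iupac_expand(pattern$elements[i])
  }, logical(1))
  sum(!ok)
}

#' Column-wise minimal IUPAC consensus of equal-length DNA strings
#'
#' Per column, the returned code is the smallest IUPAC set covering every
#' observed base (`N` when all four occur), so every input matches the
#' consensus under [iupac_match()].
#'
#' @param seqs Character vector (>= 2) of equal-length `ACGT` strings.
#' @param id Identifier for the returned pattern.
#' @return A DNA [motif_pattern()] of the common input length.
#' @examples
#' pattern_string(build_iupac_consensus(c("GAC", "GAT")))
#' @export
build_iupac_consensus <- function(seqs, id = "consensus") {
  if (length(seqs) < 2) abort("need at least 2 sequences")
  seqs <- toupper(seqs)
  n <- unique(nchar(seqs))
  if (length(n) != 1) abort("sequences must have equal length")
  chars <- do.call(rbind, strsplit(seqs, ""))
  if (!all(chars %in% c("A", "C", "G", "T"))) {
    abort("sequences must contain only A, C, G, T")
  }
  codes <- apply(chars, 2, iupac_code_for)
  motif_pattern(id, "dna", codes)
}

#' Read motif patterns from a JSON file
#'
#' The file holds an array of objects with fields `id`, `alphabet`, and
#' `elements`. Built-in patterns ([motif_patterns()]) are always available
#' regardless; this only adds user-defined ones.
#'
#' @param path Path to a JSON pattern file.
#' @return Named list of [motif_pattern()] objects.
#' @export
read_patterns <- function(path) {
  if (!file.exists(path)) abort(paste0("pattern file not found: ", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  pats <- map(raw, function(p) {
    motif_pattern(p$id, p$alphabet, unlist(p$elements))
  })
  setNames(pats, map_chr(pats, "id"))
}
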