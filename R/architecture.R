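# Segmentation of a DDxP protein into N region / module array / C region.
#
# Candidate module boundaries are the end positions of terminal-motif hits;
# the segmenter keeps the chain of boundaries with the most inter-boundary
# gaps inside the configured module-length window (ties resolved leftmost).

# Longest chain of boundary positions whose successive gaps lie in
# [min_len, max_len]. Returns the boundary vector, or NULL when no chain
# with at least one module exists. Deterministic: among equally long
# chains the leftmost (earliest boundaries) wins.
find_best_chain <- function(b, min_len, max_len) {
  m <- length(b)
  if (m < 2) return(NULL)
  len <- rep(1L, m)            # chain length in boundaries, ending at j
  pred <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    for (i in seq_len(j - 1L)) {
      gap <- b[j] - b[i]
      if (gap >= min_len && gap <= max_len && len[i] + 1L > len[j]) {
        len[j] <- len[i] + 1L   # strict > keeps the earliest predecessor
        pred[j] <- i
      }
    }
  }
  best <- max(len)
  if (best < 2L) return(NULL)
  j <- which(len == best)[1]    # earliest chain end among maxima
  chain <- j
  while (!is.na(pred[j])) {
    j <- pred[j]
    chain <- c(j, chain)
  }
  b[chain]
}

#' Classify a module length as short, long, or intermediate
#'
#' Short (`"S"`) up to `config$s_max` aa, long (`"L"`) from `config$l_min`
#' aa, `"intermediate"` in the gap between the two published ranges.
#'
#' @param length Positive integer vector of module lengths in aa.
#' @param config A [ddxp_config()].
#' @return Character vector in `{"S", "L", "intermediate"}`.
#' @examples
#' classify_size(c(136, 309, 230))
#' @export
classify_size <- function(length, config = ddxp_config()) {
  if (any(length <= 0)) abort("module length must be positive")
  dplyr::case_when(
    length <= config$s_max ~ "S",
    length >= config$l_min ~ "L",
    TRUE ~ "intermediate"
  )
}

#' Segment a protein into N region, DDxP modules, and C region
#'
#' Collects terminal-motif (Asp-Asp-x-Pro) hit ends as candidate
#' boundaries, keeps the longest chain whose gaps fall within the module
#' length window, and annotates each resulting module with its terminal
#' motif, size class, and DGDGD motif offsets. Proteins without a valid
#' chain come back with an empty module table, group `NA`, and the
#' `no_module_chain` flag.
#'
#' QC flags: `no_module_chain`, `starts_in_repeat` (chain begins within one
#' minimum module length of the N terminus, as for proteins truncated
#' inside a repeat), `intermediate_size_module`, `missing_dgdgd` (a module
#' lacks a DGDGD motif ending inside the configured upstream window), and
#' `extra_module_chain` (a second valid chain exists outside the reported
#' one).
#'
#' @param protein A one-row record tibble from [read_fasta()], or a list
#'   with `id` and `seq`.
#' @param config A [ddxp_config()].
#' @return An object of class `ddxp_architecture`: protein id and length,
#'   `n_region` / `c_region` (0-based half-open), a `modules` tibble, the
#'   group call, and `qc_flags`.
#' @examples
#' prot <- paste0(strrep("A", 150), "DDGP", strrep("L", 146), "DDGP",
#'                strrep("S", 200))
#' segment_modules(list(id = "demo", seq = prot))
#' @export
segment_modules <- function(protein, config = ddxp_config()) {
  id <- if (is.data.frame(protein)) protein$id[[1]] else protein$id
  seq <- toupper(if (is.data.frame(protein)) protein$seq[[1]] else protein$seq)
  n <- nchar(seq)
  pats <- motif_patterns(config)

  hits <- scan_motif(seq, pats$DDXP)
  boundaries <- sort(unique(hits$end))
  chain <- find_best_chain(boundaries, config$min_module_len,
                           config$max_module_len)

  qc <- character(0)
  if (is.null(chain)) {
    qc <- "no_module_chain"
    modules <- empty_module_table()
    n_region <- c(0L, n)
    c_region <- c(n, n)
    group <- NA_character_
  } else {
    k <- length(chain) - 1L
    dg_all <- scan_motif(seq, pats$DGDGD)
    modules <- map(seq_len(k), function(i) {
      s <- chain[i]; e <- chain[i + 1L]
      dg <- dg_all[dg_all$start >= s & dg_all$end <= e - 4L, , drop = FALSE]
      offs <- (e - 4L) - dg$end
      mseq <- substr(seq, s + 1L, e)
      tm <- substr(seq, e - 3L, e)
      tibble(
        module_index = i,
        start = s, end = e,
        length_aa = e - s,
        seq = mseq,
        terminal_motif = tm,
        size_class = classify_size(e - s, config),
        dgdgd_offsets = list(as.integer(offs)),
        dgdgd_hits = list(dg[, c("start", "end")]),
        type_id = NA_character_
      )
    }) |> bind_rows()
    n_region <- c(0L, chain[1])
    c_region <- c(chain[k + 1L], n)

    rtx <- scan_motif(seq, pats$RTX9)
    n_rtx <- sum(rtx$start >= c_region[1] & rtx$end <= c_region[2])
    group <- if (n_rtx >= config$min_rtx_hits) "I" else "II"

    if (chain[1] < config$min_module_len) qc <- c(qc, "starts_in_repeat")
    if (any(modules$size_class == "intermediate")) {
      qc <- c(qc, "intermediate_size_module")
    }
    w <- config$dgdgd_window
    miss <- map_lgl(modules$dgdgd_offsets,
                    function(o) !any(o >= w[1] & o <= w[2]))
    if (any(miss)) qc <- c(qc, "missing_dgdgd")
    left <- boundaries[boundaries < chain[1]]
    right <- boundaries[boundaries > chain[k + 1L]]
    if (!is.null(find_best_chain(left, config$min_module_len,
                                 config$max_module_len)) ||
        !is.null(find_best_chain(right, config$min_module_len,
                                 config$max_module_len))) {
      qc <- c(qc, "extra_module_chain")
    }
  }

  structure(
    list(protein_id = id, seq = seq, length = n,
         n_region = as.integer(n_region), modules = modules,
         c_region = as.integer(c_region), group = group,
         qc_flags = qc, config = config),
    class = "ddxp_architecture"
  )
}

empty_module_table <- function() {
  tibble(
    module_index = integer(0), start = integer(0), end = integer(0),
    length_aa = integer(0), seq = character(0),
    terminal_motif = character(0), size_class = character(0),
    dgdgd_offsets = list(), dgdgd_hits = list(), type_id = character(0)
  )
}

#' Group-I / group-II call for a segmented protein
#'
#' Group I means at least `config$min_rtx_hits` RTX nonapeptide hits fall
#' entirely inside the C region; group II otherwise; `NA` when the protein
#' has no modules.
#'
#' @param arch A `ddxp_architecture`.
#' @param config A [ddxp_config()].
#' @return `"I"`, `"II"`, or `NA`.
#' @export
assign_group <- function(arch, config = ddxp_config()) {
  stopifnot(inherits(arch, "ddxp_architecture"))
  if (nrow(arch$modules) == 0) return(NA_character_)
  rtx <- scan_motif(arch$seq, motif_patterns(config)$RTX9)
  n_rtx <- sum(rtx$start >= arch$c_region[1] & rtx$end <= arch$c_region[2])
  if (n_rtx >= config$min_rtx_hits) "I" else "II"
}

#' QC flags of a segmented protein
#'
#' @param arch A `ddxp_architecture`.
#' @return Character vector of flags (possibly empty); see
#'   [segment_modules()] for their meaning.
#' @export
qc_flags <- function(arch) {
  stopifnot(inherits(arch, "ddxp_architecture"))
  arch$qc_flags
}

#' @export
print.ddxp_architecture <- function(x, ...) {
  cat(sprintf("<ddxp_architecture> %s (%d aa)\n", x$protein_id, x$length))
  cat(sprintf("  N region  [%d, %d)\n", x$n_region[1], x$n_region[2]))
  cat(sprintf("  modules   %d\n", nrow(x$modules)))
  if (nrow(x$modules) > 0) {
    for (i in seq_len(nrow(x$modules))) {
      m <- x$modules[i, ]
      cat(sprintf("    %2d [%d, %d) %d aa %s %s\n", m$module_index,
                  m$start, m$end, m$length_aa, m$size_class,
                  m$terminal_motif))
    }
  }
  cat(sprintf("  C region  [%d, %d)\n", x$c_region[1], x$c_region[2]))
  cat(sprintf("  group     %s\n", ifelse(is.na(x$group), "NA", x$group)))
  if (length(x$qc_flags) > 0) {
    cat("  qc        ", paste(x$qc_flags, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Segment every protein of a record table
#'
#' Data-frame-first wrapper around [segment_modules()]: one output row per
#' module (proteins without modules contribute a single row with `NA`
#' module fields so their QC flags are not lost). The full architecture
#' objects are attached as the `"architectures"` attribute, named by
#' protein id.
#'
#' @param seqs Record tibble from [read_fasta()] (protein alphabet).
#' @param config A [ddxp_config()].
#' @return Tibble with columns `protein_id`, `protein_length`,
#'   `module_index`, `module_id`, `start`, `end`, `length_aa`, `seq`,
#'   `terminal_motif`, `size_class`, `dgdgd_offsets` (list), `group`,
#'   `qc_flags` (collapsed string).
#' @export
scan_proteins <- function(seqs, config = ddxp_config()) {
  stopifnot(is.data.frame(seqs), nrow(seqs) > 0)
  archs <- map(seq_len(nrow(seqs)),
               function(i) segment_modules(seqs[i, ], config))
  names(archs) <- seqs$id
  rows <- map(archs, function(a) {
    qc <- paste(a$qc_flags, collapse = ";")
    if (nrow(a$modules) == 0) {
      tibble(protein_id = a$protein_id, protein_length = a$length,
             module_index = NA_integer_, module_id = NA_character_,
             start = NA_integer_, end = NA_integer_,
             length_aa = NA_integer_, seq = NA_character_,
             terminal_motif = NA_character_, size_class = NA_character_,
             dgdgd_offsets = list(integer(0)),
             group = a$group, qc_flags = qc)
    } else {
      a$modules |>
        mutate(protein_id = a$protein_id, protein_length = a$length,
               module_id = sprintf("%s|%d|%d-%d", a$protein_id,
                                   .data$module_index, .data$start,
                                   .data$end),
               group = a$group, qc_flags = qc) |>
        select("protein_id", "protein_length", "module_index", "module_id",
               "start", "end", "length_aa", "seq", "terminal_motif",
               "size_class", "dgdgd_offsets", "group", "qc_flags")
    }
  })
  out <- bind_rows(rows)
  attr(out, "architectures") <- archs
  out
}
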