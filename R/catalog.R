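# The packaged catalog of published DDxP repeat modules and summary
# statistics over it. The catalog stores the PRINTED size labels; the
# length classifier is applied separately and disagreements are reported,
# never silently corrected.

#' Load the packaged DDxP repeat catalog
#'
#' A machine-readable table of the 85 published repeat modules: genus,
#' repeat id, length (aa), printed size label (S/L), solo and het flags,
#' and the terminal tetrapeptide. The id series intentionally mirrors the
#' published one (e.g. there is no P14). Fields are validated on load.
#'
#' @return Tibble with columns `genus`, `repeat_id`, `length_aa`,
#'   `size_label`, `solo`, `het`, `terminal_motif`.
#' @examples
#' cat85 <- load_catalog()
#' dplyr::filter(cat85, repeat_id == "P5")
#' @export
load_catalog <- function() {
  path <- system.file("extdata", "ddxp_repeat_catalog.tsv",
                      package = "ddxpscan", mustWork = TRUE)
  x <- as_tibble(read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(
                              genus = "character", repeat_id = "character",
                              length_aa = "integer", size_label = "character",
                              solo = "logical", het = "logical",
                              terminal_motif = "character")))
  ok <- all(c("genus", "repeat_id", "length_aa", "size_label", "solo",
              "het", "terminal_motif") %in% names(x)) &&
    !anyNA(x$length_aa) && all(x$length_aa > 0) &&
    !any(duplicated(x$repeat_id)) &&
    all(x$size_label %in% c("S", "L")) &&
    all(nchar(x$terminal_motif) == 4L)
  if (!ok) abort("packaged repeat catalog failed integrity checks")
  x
}

#' Summary statistics over the repeat catalog
#'
#' Computes entry totals, counts per printed size label, the solo count
#' and fraction, terminal motifs that do not conform to Asp-Asp-x-Pro,
#' length ranges overall and per classifier class ([classify_size()]
#' applied to the lengths), and the entries whose printed label disagrees
#' with the classifier. Discrepancies internal to the published account
#' (the printed "14/17 long modules" against the table's 16 long rows; the
#' serine in Rb4's printed motif) are carried as notes.
#'
#' @param entries Catalog tibble from [load_catalog()].
#' @param config A [ddxp_config()] (classifier thresholds).
#' @return A list of class `ddxp_catalog_stats`.
#' @export
catalog_stats <- function(entries = load_catalog(), config = ddxp_config()) {
  stopifnot(is.data.frame(entries), nrow(entries) > 0)
  conform <- grepl("^DD.P$", entries$terminal_motif)
  classified <- classify_size(entries$length_aa, config)
  class_ranges <- tibble(class = classified, length_aa = entries$length_aa) |>
    group_by(.data$class) |>
    summarise(n = dplyr::n(), min_aa = min(.data$length_aa),
              max_aa = max(.data$length_aa), .groups = "drop")
  disagree <- entries |>
    mutate(classified = classified) |>
    filter(.data$size_label != .data$classified) |>
    select("repeat_id", "length_aa", printed = "size_label", "classified")
  structure(
    list(
      n_entries = nrow(entries),
      n_by_label = table(entries$size_label),
      n_solo = sum(entries$solo),
      solo_fraction = mean(entries$solo),
      n_het = sum(entries$het),
      motif_exceptions = entries |>
        filter(!conform) |>
        select("repeat_id", "terminal_motif"),
      length_range = c(min = min(entries$length_aa),
                       max = max(entries$length_aa)),
      class_ranges = class_ranges,
      label_disagreements = disagree,
      notes = c(
        "printed text counts 17 L modules; the table yields 16 L-labeled rows",
        "Rb4's printed motif DSGP carries serine where the text says glycine"
      )
    ),
    class = "ddxp_catalog_stats"
  )
}

#' @export
print.ddxp_catalog_stats <- function(x, ...) {
  cat("<ddxp_catalog_stats>\n")
  cat(sprintf("  entries         %d (S: %d, L: %d)\n", x$n_entries,
              x$n_by_label[["S"]], x$n_by_label[["L"]]))
  cat(sprintf("  solo            %d (%.1f%%)\n", x$n_solo,
              100 * x$solo_fraction))
  cat(sprintf("  het             %d\n", x$n_het))
  cat(sprintf("  length range    %d-%d aa\n", x$length_range[["min"]],
              x$length_range[["max"]]))
  cat("  classifier ranges:\n")
  for (i in seq_len(nrow(x$class_ranges))) {
    r <- x$class_ranges[i, ]
    cat(sprintf("    %-12s n=%2d  %d-%d aa\n", r$class, r$n, r$min_aa,
                r$max_aa))
  }
  cat("  terminal-motif exceptions:",
      paste(x$motif_exceptions$repeat_id, collapse = ", "), "\n")
  if (nrow(x$label_disagreements) > 0) {
    cat("  label vs classifier disagreements:",
        paste(sprintf("%s (%d aa, printed %s, classified %s)",
                      x$label_disagreements$repeat_id,
                      x$label_disagreements$length_aa,
                      x$label_disagreements$printed,
                      x$label_disagreements$classified), collapse = "; "),
        "\n")
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' @export
glance.ddxp_catalog_stats <- function(x, ...) {
  tibble(
    n_entries = x$n_entries,
    n_short = unname(x$n_by_label[["S"]]),
    n_long = unname(x$n_by_label[["L"]]),
    n_solo = x$n_solo,
    solo_fraction = x$solo_fraction,
    n_het = x$n_het,
    n_motif_exceptions = nrow(x$motif_exceptions),
    min_length_aa = unname(x$length_range[["min"]]),
    max_length_aa = unname(x$length_range[["max"]]),
    n_label_disagreements = nrow(x$label_disagreements)
  )
}
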