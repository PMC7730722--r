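# broom-style accessors and ggplot2 methods for scanner results.

#' Tidy a protein architecture into one row per segment
#'
#' @param x A `ddxp_architecture` from [segment_modules()].
#' @param ... Unused.
#' @return Tibble with columns `protein_id`, `segment`, `start`, `end`
#'   (0-based half-open), `length_aa`, `terminal_motif`, `size_class`.
#' @export
tidy.ddxp_architecture <- function(x, ...) {
  rows <- list(tibble(
    protein_id = x$protein_id, segment = "N",
    start = x$n_region[1], end = x$n_region[2],
    length_aa = x$n_region[2] - x$n_region[1],
    terminal_motif = NA_character_, size_class = NA_character_))
  if (nrow(x$modules) > 0) {
    rows[[2]] <- x$modules |>
      mutate(protein_id = x$protein_id,
             segment = sprintf("module_%d", .data$module_index)) |>
      select("protein_id", "segment", "start", "end", "length_aa",
             "terminal_motif", "size_class")
  }
  rows[[length(rows) + 1L]] <- tibble(
    protein_id = x$protein_id, segment = "C",
    start = x$c_region[1], end = x$c_region[2],
    length_aa = x$c_region[2] - x$c_region[1],
    terminal_motif = NA_character_, size_class = NA_character_)
  bind_rows(rows)
}

#' One-row summary of a protein architecture
#'
#' @inheritParams tidy.ddxp_architecture
#' @return Tibble with protein id, length, module counts by size class,
#'   group call, and collapsed QC flags.
#' @export
glance.ddxp_architecture <- function(x, ...) {
  tibble(
    protein_id = x$protein_id,
    length_aa = x$length,
    n_modules = nrow(x$modules),
    n_short = sum(x$modules$size_class == "S"),
    n_long = sum(x$modules$size_class == "L"),
    n_intermediate = sum(x$modules$size_class == "intermediate"),
    group = x$group,
    qc_flags = paste(x$qc_flags, collapse = ";")
  )
}

#' Plot a protein architecture as a segment diagram
#'
#' N and C regions in grey, repeat modules coloured by size class, with
#' the terminal tetrapeptide labelled on each module.
#'
#' @param object A `ddxp_architecture`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ddxp_architecture <- function(object, ...) {
  seg <- tidy(object)
  seg$kind <- ifelse(seg$segment %in% c("N", "C"), "flank",
                     seg$size_class)
  ggplot(seg) +
    geom_rect(aes(xmin = .data$start, xmax = .data$end,
                  ymin = 0, ymax = 1, fill = .data$kind),
              colour = "grey20", linewidth = 0.2) +
    geom_text(aes(x = (.data$start + .data$end) / 2, y = 0.5,
                  label = ifelse(is.na(.data$terminal_motif),
                                 .data$segment, .data$terminal_motif)),
              size = 3) +
    scale_fill_manual(values = c(flank = "grey85", S = "#66c2a5",
                                 L = "#fc8d62", intermediate = "#8da0cb"),
                      name = NULL) +
    labs(x = "position (aa)", y = NULL, title = object$protein_id) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid.major.y = element_blank(),
          panel.grid.minor.y = element_blank())
}

#' Plot catalog module lengths by genus
#'
#' Dot plot of the packaged repeat lengths with the short/long classifier
#' cutoffs drawn as dashed lines.
#'
#' @param entries Catalog tibble from [load_catalog()].
#' @param config A [ddxp_config()].
#' @return A ggplot object.
#' @export
plot_catalog_lengths <- function(entries = load_catalog(),
                                 config = ddxp_config()) {
  entries$classified <- classify_size(entries$length_aa, config)
  ggplot(entries, aes(x = .data$genus, y = .data$length_aa,
                      colour = .data$classified)) +
    geom_jitter(width = 0.15, height = 0, size = 2) +
    geom_hline(yintercept = c(config$s_max, config$l_min),
               linetype = "dashed", colour = "grey40") +
    labs(x = NULL, y = "module length (aa)", colour = "class") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
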