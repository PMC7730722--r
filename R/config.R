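#' Scanner and report configuration
#'
#' Collects every tunable threshold used by the motif scanner, the module
#' segmenter, the repeat typing step, and the TSD detector. Defaults follow
#' the published description of the DDxP protein family: module lengths
#' bracket the observed 136--309 aa range with margin, the short/long size
#' cutoffs sit at 215 and 243 aa, the DGDGD motif is expected 11--19 aa
#' upstream of the terminal tetrapeptide, proteins with at least two RTX
#' nonapeptide hits in the C region are called group I, and flanking
#' target-site-duplication copies may diverge by at most 4 of 18 bases.
#'
#' @param min_module_len,max_module_len Admissible module length in aa when
#'   chaining candidate boundaries (defaults 120 and 350).
#' @param x_allowed Optional character vector restricting the third (wildcard)
#'   residue of the terminal Asp-Asp-x-Pro motif; `NULL` (default) admits any
#'   amino acid.
#' @param relaxed_terminal If `TRUE`, the terminal motif tolerates one
#'   mismatch at its second position only (admits the divergent DSGP, DTGP,
#'   DVGP variants). Off by default.
#' @param s_max Maximum length (aa) of a short (S) module; default 215.
#' @param l_min Minimum length (aa) of a long (L) module; default 243.
#'   Lengths strictly between `s_max` and `l_min` classify as
#'   `"intermediate"`.
#' @param dgdgd_window Integer length-2 vector: admissible distance in aa
#'   between the end of a DGDGD hit and the start of the terminal motif.
#' @param min_rtx_hits Minimum RTX nonapeptide hits in the C region for a
#'   group-I call; default 2.
#' @param max_tsd_mismatches Maximum Hamming mismatches tolerated between the
#'   two 18-bp copies of a target site duplication; default 4.
#' @param identity_threshold Pairwise identity above which (strictly) two
#'   modules join the same repeat type; default 0.70.
#' @param het_divergence Mean within-type divergence above which a type is
#'   flagged heterogeneous; default 0.05.
#' @param het_marginal Upper bound of the divergence band flagged
#'   `het_marginal` (types between `het_divergence` and this value are het,
#'   but sit in a band the family description leaves open); default 0.15.
#'
#' @return A list of class `ddxp_config`.
#' @examples
#' cfg <- ddxp_config(x_allowed = c("G", "T", "V"))
#' cfg$min_module_len
#' @export
ddxp_config <- function(min_module_len = 120L,
                        max_module_len = 350L,
                        x_allowed = NULL,
                        relaxed_terminal = FALSE,
                        s_max = 215L,
                        l_min = 243L,
                        dgdgd_window = c(11L, 19L),
                        min_rtx_hits = 2L,
                        max_tsd_mismatches = 4L,
                        identity_threshold = 0.70,
                        het_divergence = 0.05,
                        het_marginal = 0.15) {
  stopifnot(
    min_module_len > 0, max_module_len >= min_module_len,
    s_max > 0, l_min > s_max,
    length(dgdgd_window) == 2, dgdgd_window[1] >= 0,
    dgdgd_window[2] >= dgdgd_window[1],
    min_rtx_hits >= 1, max_tsd_mismatches >= 0,
    identity_threshold >= 0, identity_threshold <= 1,
    het_divergence >= 0, het_marginal >= het_divergence
  )
  if (!is.null(x_allowed)) {
    x_allowed <- toupper(x_allowed)
    bad <- setdiff(x_allowed, protein_letters())
    if (length(bad) > 0) {
      abort(paste0("x_allowed contains non-amino-acid letters: ",
                   paste(bad, collapse = ", ")))
    }
  }
  structure(
    list(
      min_module_len = as.integer(min_module_len),
      max_module_len = as.integer(max_module_len),
      x_allowed = x_allowed,
      relaxed_terminal = isTRUE(relaxed_terminal),
      s_max = as.integer(s_max),
      l_min = as.integer(l_min),
      dgdgd_window = as.integer(dgdgd_window),
      min_rtx_hits = as.integer(min_rtx_hits),
      max_tsd_mismatches = as.integer(max_tsd_mismatches),
      identity_threshold = identity_threshold,
      het_divergence = het_divergence,
      het_marginal = het_marginal
    ),
    class = "ddxp_config"
  )
}

#' @export
print.ddxp_config <- function(x, ...) {
  cat("<ddxp_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-20s %s\n", nm,
                if (is.null(v)) "NULL" else paste(v, collapse = ", ")))
  }
  invisible(x)
}
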