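# Growth-by-insertion simulator: builds an ancestral "empty" gene carrying
# one endonuclease target site, then grows it by module insertion at
# target-site duplications, tandem amplification of module+TSD units, and
# point mutation. All events and true module coordinates are logged so
# scanner output can be scored against ground truth.
#
# The cut geometry is modelled as two cuts 18 bp apart (6 bp upstream of
# the DDxP-encoding dodecamer plus the dodecamer itself); repair of the
# staggered ends duplicates the 18-bp overhang, so each insertion leaves
# identical 18-bp direct repeats flanking the new module.

aa20 <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

stop_codons <- function() c("TAA", "TAG", "TGA")

codons_by_aa <- function() {
  if (is.null(the$codons_by_aa)) {
    gc <- genetic_code_11()
    the$codons_by_aa <- split(names(gc), unname(gc))
  }
  the$codons_by_aa
}

#' Randomly back-translate a protein to coding DNA
#'
#' One uniformly drawn synonymous codon (bacterial code, table 11) per
#' residue, so the result translates back to the input and contains no
#' stop codons. Draws from the current RNG state.
#'
#' @param protein Protein string over the 20 standard amino acids.
#' @return DNA string of length `3 * nchar(protein)`.
#' @examples
#' set.seed(1)
#' translate_cds(backtranslate("DDGP"))
#' @export
backtranslate <- function(protein) {
  tab <- codons_by_aa()
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(a) {
    cands <- tab[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1)), collapse = "")
}

random_protein <- function(n) {
  paste(sample(aa20(), n, replace = TRUE), collapse = "")
}

#' Simulation configuration
#'
#' Parameters of the growth-by-insertion simulator. The published account
#' of the family gives no insertion/amplification/mutation rates, so these
#' are user parameters; defaults produce a mid-sized repeat array. The
#' module length range brackets the observed 136--309 aa catalog range;
#' `phe_bias` reflects the predominance of TTC/TTT at the first three
#' target bases; N and C region lengths are typical of the family's
#' shorter members.
#'
#' @param seed Integer seed; every simulator draw derives from it.
#' @param n_insertions Number of module insertion events (>= 0).
#' @param amplification_copies Tandem copy count each inserted module is
#'   amplified to (1 = no amplification).
#' @param mutation_rate Per-base substitution probability in `[0, 1)`,
#'   applied once after all insertions.
#' @param module_length_range Length-2 aa range modules are drawn from.
#' @param phe_bias Probability that target bases 1--3 are TTC or TTT.
#' @param n_region_len,c_region_len N and C region lengths in aa.
#' @param avoid_stops Redraw substitutions that would create a stop codon.
#' @param max_tries Rejection-sampling bound for sequence generation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_insertions = 2L,
                       amplification_copies = 3L,
                       mutation_rate = 0,
                       module_length_range = c(130L, 310L),
                       phe_bias = 0.9,
                       n_region_len = 200L,
                       c_region_len = 300L,
                       avoid_stops = TRUE,
                       max_tries = 10000L) {
  stopifnot(
    n_insertions >= 0, amplification_copies >= 1,
    mutation_rate >= 0, mutation_rate < 1,
    length(module_length_range) == 2,
    module_length_range[1] >= 30, # room for body + DGDGD + terminal motif
    module_length_range[2] >= module_length_range[1],
    phe_bias >= 0, phe_bias <= 1,
    n_region_len >= 10, c_region_len >= 1, max_tries >= 1
  )
  structure(
    list(seed = as.integer(seed),
         n_insertions = as.integer(n_insertions),
         amplification_copies = as.integer(amplification_copies),
         mutation_rate = mutation_rate,
         module_length_range = as.integer(module_length_range),
         phe_bias = phe_bias,
         n_region_len = as.integer(n_region_len),
         c_region_len = as.integer(c_region_len),
         avoid_stops = isTRUE(avoid_stops),
         max_tries = as.integer(max_tries)),
    class = "sim_config"
  )
}

# one random 18-bp target conforming to the recognition consensus, with
# stop-free codon 2 and the configured phenylalanine bias at codon 1
sample_target <- function(phe_bias) {
  c1 <- if (runif(1) < phe_bias) {
    sample(c("TTC", "TTT"), 1)
  } else {
    sample(c("ATC", "ATT", "GTC", "GTT"), 1)
  }
  repeat {
    c2 <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                collapse = "")
    if (!c2 %in% stop_codons()) break
  }
  paste0(c1, c2,
         sample(c("GAC", "GAT"), 1),
         sample(c("GAC", "GAT"), 1),
         paste0("G", sample(c("G", "T"), 1), sample(c("A", "C", "G", "T"), 1)),
         paste0("CC", sample(c("A", "C", "G"), 1)))
}

#' Build an ancestral ("empty") gene with one planted target site
#'
#' The CDS encodes an N region, a single 18-bp endonuclease target
#' (conforming to the recognition consensus, translating to a peptide
#' ending Asp-Asp-x-Pro), and a C region, closed by a TAA stop. The gene
#' is rejection-sampled until its translation contains exactly one DDxP
#' occurrence -- the planted one -- so the scanner sees no spurious
#' boundaries.
#'
#' @param config A [sim_config()]. Note this function draws from the
#'   current RNG state; seed it (or use [simulate_lineage()], which seeds
#'   from `config$seed`).
#' @return List with `cds` and `protein` record tibbles, `pairing`, and
#'   `target_site` (0-based CDS start/end of the planted 18-mer).
#' @export
make_ancestral_gene <- function(config = sim_config()) {
  pat <- motif_patterns()$DDXP
  n_len <- config$n_region_len
  c_len <- config$c_region_len
  for (k in seq_len(config$max_tries)) {
    target <- sample_target(config$phe_bias)
    n_aa <- paste0("M", random_protein(n_len - 1L))
    c_aa <- random_protein(c_len)
    prot <- paste0(n_aa, translate_cds(target), c_aa)
    hits <- scan_motif(prot, pat)
    if (nrow(hits) == 1 && hits$end == n_len + 6L) {
      cds <- paste0(backtranslate(n_aa), target, backtranslate(c_aa), "TAA")
      return(list(
        cds = tibble(id = "sim", description = "simulated ancestral gene",
                     seq = cds, alphabet = "dna"),
        protein = tibble(id = "sim",
                         description = "simulated ancestral protein",
                         seq = prot, alphabet = "protein"),
        pairing = cds_pairing("sim", "sim", 0L),
        target_site = c(3L * n_len, 3L * n_len + 18L)
      ))
    }
  }
  abort("failed to generate an ancestral gene without spurious DDxP motifs")
}

# module body (coding DNA, length divisible by 3) whose translation joined
# to the 6-aa target peptide carries exactly the terminal DDxP plus a
# DGDGD motif 11-19 aa upstream of it
sample_module_body <- function(total_len_aa, target, config) {
  stopifnot(total_len_aa >= 30)
  body_len <- total_len_aa - 6L
  tsd_aa <- translate_cds(target)
  pat <- motif_patterns()$DDXP
  for (k in seq_len(config$max_tries)) {
    aa <- sample(aa20(), body_len, replace = TRUE)
    off <- sample(11:19, 1)
    dg_end <- total_len_aa - 4L - off   # 0-based module coords
    aa[(dg_end - 4L):dg_end] <- c("D", "G", "D", "G", "D")
    mod_aa <- paste0(paste(aa, collapse = ""), tsd_aa)
    hits <- scan_motif(mod_aa, pat)
    if (nrow(hits) == 1 && hits$end == total_len_aa) {
      return(backtranslate(paste(aa, collapse = "")))
    }
  }
  abort("failed to generate a module body free of internal DDxP motifs")
}

#' Insert a DNA module at an endonuclease target site
#'
#' Models the staggered cut and repair: the 18-bp target at `site` is
#' duplicated, and the module body lands between the two copies, so the
#' emitted CDS reads prefix + TSD + body + TSD + suffix. The reading frame
#' is preserved and the translated protein gains one module of
#' `nchar(module_body)/3 + 6` aa ending Asp-Asp-x-Pro.
#'
#' @param cds DNA string (frame 0 coding sequence).
#' @param site 0-based CDS position of the 18-bp target; must be a codon
#'   boundary and match the recognition consensus.
#' @param module_body Coding DNA, length divisible by 3, no stop codons
#'   and no DDxP in its translation.
#' @return List with `cds` (modified sequence), `module_span` (0-based
#'   half-open CDS interval of the new module, body plus downstream TSD),
#'   `tsd_spans` (left and right copy intervals), and `event` (one-row
#'   tibble).
#' @export
simulate_insertion <- function(cds, site, module_body) {
  cds <- toupper(cds); module_body <- toupper(module_body)
  n <- nchar(cds)
  if (site < 0 || site + 18L > n) abort("target site outside the sequence")
  if (site %% 3L != 0L) abort("target site is not on a codon boundary")
  target <- substr(cds, site + 1L, site + 18L)
  if (!iupac_match(target, tsd18_pattern())) {
    abort("sequence at the target site does not match the recognition consensus")
  }
  blen <- nchar(module_body)
  if (blen %% 3L != 0L) abort("module body length must be divisible by 3")
  body_aa <- translate_cds(module_body)
  if (grepl("\\*", body_aa)) abort("module body contains a stop codon")
  if (nrow(scan_motif(body_aa, motif_patterns()$DDXP)) > 0) {
    abort("module body translation contains a DDxP motif")
  }
  new_cds <- paste0(substr(cds, 1L, site + 18L), module_body, target,
                    substr(cds, site + 19L, n))
  module_span <- c(site + 18L, site + 36L + blen)
  list(
    cds = new_cds,
    module_span = as.integer(module_span),
    tsd_spans = list(left = c(site, site + 18L),
                     right = c(site + 18L + blen, site + 36L + blen)),
    event = tibble(kind = "insertion", site = site,
                   length = blen + 18L, copies = NA_integer_,
                   n_substitutions = NA_integer_)
  )
}

#' Tandem-amplify a module together with one flanking TSD
#'
#' The unit spanning the module body plus its downstream TSD copy is
#' duplicated `k - 1` further times head-to-tail, so the module count
#' rises by `k - 1` and every junction carries a TSD copy.
#'
#' @param cds DNA string.
#' @param module_span 0-based half-open CDS interval of the module (body
#'   plus downstream TSD), e.g. from [simulate_insertion()].
#' @param k Total copy count after amplification (>= 1; `k = 1` is the
#'   identity).
#' @return List with `cds`, `module_spans` (intervals of all `k` copies),
#'   and `event`.
#' @export
simulate_amplification <- function(cds, module_span, k) {
  cds <- toupper(cds)
  s <- module_span[1]; e <- module_span[2]
  if (s < 0 || e > nchar(cds) || e <= s) abort("invalid module span")
  if (k < 1) abort("k must be >= 1")
  unit <- substr(cds, s + 1L, e)
  L <- e - s
  new_cds <- paste0(substr(cds, 1L, e), strrep(unit, k - 1L),
                    substr(cds, e + 1L, nchar(cds)))
  spans <- map(seq_len(k), function(j) c(s + (j - 1L) * L, s + j * L))
  list(
    cds = new_cds,
    module_spans = spans,
    event = tibble(kind = "amplification", site = s, length = L,
                   copies = as.integer(k), n_substitutions = NA_integer_)
  )
}

#' Apply i.i.d. point substitutions to a coding sequence
#'
#' Each base (the final stop codon excluded) is substituted with
#' probability `rate` by a uniformly drawn different base. When
#' `avoid_stops` is set, substitutions that would create an in-frame stop
#' codon are re-drawn among the remaining bases (and skipped if none
#' works), so the emitted CDS still translates without internal stops.
#'
#' @param cds DNA string (frame 0, ending in a stop codon).
#' @param rate Per-base substitution probability in `[0, 1)`.
#' @param avoid_stops Logical; default `TRUE`.
#' @return List with `cds`, `positions` (0-based substituted positions),
#'   and `event`.
#' @export
simulate_mutation <- function(cds, rate, avoid_stops = TRUE) {
  stopifnot(rate >= 0, rate < 1)
  cds <- toupper(cds)
  n <- nchar(cds)
  bases <- strsplit(cds, "")[[1]]
  mutable <- n - 3L   # spare the terminal stop codon
  hit <- which(runif(mutable) < rate)
  done <- integer(0)
  for (pos in hit) {
    alts <- sample(setdiff(c("A", "C", "G", "T"), bases[pos]))
    for (alt in alts) {
      old <- bases[pos]
      bases[pos] <- alt
      if (avoid_stops) {
        cstart <- pos - ((pos - 1L) %% 3L)
        codon <- paste(bases[cstart:(cstart + 2L)], collapse = "")
        if (codon %in% stop_codons()) {
          bases[pos] <- old
          next
        }
      }
      done <- c(done, pos - 1L)
      break
    }
  }
  list(
    cds = paste(bases, collapse = ""),
    positions = done,
    event = tibble(kind = "mutation", site = NA_integer_,
                   length = NA_integer_, copies = NA_integer_,
                   n_substitutions = length(done))
  )
}

shift_at <- function(x, at, by) ifelse(x >= at, x + by, x)

# shift a [start, end) interval iff it begins at/after the growth point;
# an interval ending exactly at the growth point stays put (new material
# lands after it)
shift_interval_cols <- function(df, start_col, end_col, at, by) {
  moved <- df[[start_col]] >= at
  df[[start_col]][moved] <- df[[start_col]][moved] + by
  df[[end_col]][moved] <- df[[end_col]][moved] + by
  df
}

#' Simulate a full gene lineage with ground truth
#'
#' Builds an ancestral gene, performs `n_insertions` module insertions
#' (each at a target drawn uniformly from the TSD copies present at that
#' moment, each followed by amplification to `amplification_copies`
#' copies), then applies point mutation at `mutation_rate`. Deterministic
#' per `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `cds`, `protein`, `pairing`, and `truth`; `truth`
#'   holds `events` (ordered tibble), `modules` (tibble of true module
#'   coordinates, CDS and protein), `tsds` (tibble of flanking duplication
#'   interval pairs, CDS coordinates), and `target_sites` (0-based starts
#'   of all TSD copies).
#' @examples
#' lin <- simulate_lineage(sim_config(seed = 7, n_insertions = 1,
#'                                    amplification_copies = 2))
#' lin$truth$modules
#' @export
simulate_lineage <- function(config = sim_config()) {
  set.seed(config$seed)
  anc <- make_ancestral_gene(config)
  cds <- anc$cds$seq
  sites <- anc$target_site[1]
  mods <- tibble(cds_start = integer(0), cds_end = integer(0))
  tsds <- tibble(left_start = integer(0), left_end = integer(0),
                 right_start = integer(0), right_end = integer(0))
  events <- list(tibble(kind = "ancestral", site = anc$target_site[1],
                        length = nchar(cds), copies = NA_integer_,
                        n_substitutions = NA_integer_))

  for (j in seq_len(config$n_insertions)) {
    site <- sites[sample.int(length(sites), 1L)]
    total_len <- sample(seq(config$module_length_range[1],
                            config$module_length_range[2]), 1L)
    target <- substr(cds, site + 1L, site + 18L)
    body <- sample_module_body(total_len, target, config)
    ins <- simulate_insertion(cds, site, body)
    cds <- ins$cds
    blen <- nchar(body)
    grow <- blen + 18L
    at <- site + 18L
    sites <- unique(c(shift_at(sites, at, grow), at + blen))
    mods <- shift_interval_cols(mods, "cds_start", "cds_end", at, grow)
    tsds <- shift_interval_cols(tsds, "left_start", "left_end", at, grow)
    tsds <- shift_interval_cols(tsds, "right_start", "right_end", at, grow)
    ms <- ins$module_span[1]; me <- ins$module_span[2]
    mods <- bind_rows(mods, tibble(cds_start = ms, cds_end = me))
    tsds <- bind_rows(tsds, tibble(
      left_start = ins$tsd_spans$left[1], left_end = ins$tsd_spans$left[2],
      right_start = ins$tsd_spans$right[1], right_end = ins$tsd_spans$right[2]))
    events[[length(events) + 1L]] <- ins$event

    k <- config$amplification_copies
    if (k > 1) {
      amp <- simulate_amplification(cds, c(ms, me), k)
      cds <- amp$cds
      L <- me - ms
      grow2 <- (k - 1L) * L
      sites <- unique(c(shift_at(sites, me, grow2),
                        me + seq_len(k - 1L) * L - 18L))
      mods <- shift_interval_cols(mods, "cds_start", "cds_end", me, grow2)
      tsds <- shift_interval_cols(tsds, "left_start", "left_end", me, grow2)
      tsds <- shift_interval_cols(tsds, "right_start", "right_end", me, grow2)
      extra <- map(seq_len(k - 1L), function(jj) {
        ne <- me + jj * L
        list(mod = tibble(cds_start = ne - L, cds_end = ne),
             tsd = tibble(left_start = ne - L - 18L, left_end = ne - L,
                          right_start = ne - 18L, right_end = ne))
      })
      mods <- bind_rows(mods, bind_rows(map(extra, "mod")))
      tsds <- bind_rows(tsds, bind_rows(map(extra, "tsd")))
      events[[length(events) + 1L]] <- amp$event
    }
  }

  if (config$mutation_rate > 0) {
    mut <- simulate_mutation(cds, config$mutation_rate, config$avoid_stops)
    cds <- mut$cds
    events[[length(events) + 1L]] <- mut$event
  }

  mods <- arrange(mods, .data$cds_start) |>
    mutate(start = .data$cds_start %/% 3L, end = .data$cds_end %/% 3L)
  tsds <- arrange(tsds, .data$left_start)

  prot <- sub("\\*$", "", translate_cds(cds))
  if (config$mutation_rate == 0 && nrow(mods) > 0) {
    # sanity: planted boundaries are the only DDxP occurrences
    n_hits <- nrow(scan_motif(prot, motif_patterns()$DDXP))
    if (n_hits != nrow(mods) + 1L) {
      abort("internal error: simulated gene has unexpected DDxP occurrences")
    }
  }

  list(
    cds = tibble(id = "sim", description = "simulated gene",
                 seq = cds, alphabet = "dna"),
    protein = tibble(id = "sim", description = "simulated protein",
                     seq = prot, alphabet = "protein"),
    pairing = cds_pairing("sim", "sim", 0L),
    truth = list(
      events = bind_rows(events),
      modules = mods,
      tsds = tsds,
      target_sites = sort(sites)
    )
  )
}
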