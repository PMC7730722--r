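test_that("planted module arrays are segmented at exactly the planted spans", {
  # N(200) + 3 x 180-aa modules + C(300)
  prot <- build_protein(200, rep(list(strrep("L", 176)), 3), 300)
  arch <- segment_modules(list(id = "p", seq = prot))
  expect_equal(nrow(arch$modules), 3)
  expect_equal(arch$modules$start, c(200L, 380L, 560L))
  expect_equal(arch$modules$end, c(380L, 560L, 740L))
  expect_equal(arch$n_region, c(0L, 200L))
  expect_equal(arch$c_region, c(740L, 1040L))
  expect_equal(unique(arch$modules$terminal_motif), "DDGP")
  expect_equal(unique(arch$modules$size_class), "S")
  # tiling reconstructs the protein
  expect_equal(paste0(substr(prot, 1, 200),
                      paste(arch$modules$seq, collapse = ""),
                      substr(prot, 741, nchar(prot))), prot)
})

test_that("a spurious terminal motif that cannot chain is rejected", {
  # 340-aa modules: a spurious DDGP ending 30 aa before the first true
  # boundary can link neither forward to it (gap 30 < 120) nor across it
  # (gap 370 > 350), so segmentation is unchanged
  base <- build_protein(100, rep(list(strrep("L", 336)), 3), 300)
  spur <- paste0(substr(base, 1, 66), "DDGP", substr(base, 71, nchar(base)))
  arch <- segment_modules(list(id = "p", seq = spur))
  expect_equal(nrow(arch$modules), 3)
  expect_equal(arch$modules$start[1], 100L)
  expect_equal(arch$modules$end, c(440L, 780L, 1120L))
})

test_that("module-free proteins return an empty architecture with a flag", {
  arch <- segment_modules(list(id = "p", seq = strrep("A", 400)))
  expect_equal(nrow(arch$modules), 0)
  expect_true(is.na(arch$group))
  expect_equal(qc_flags(arch), "no_module_chain")
  expect_equal(arch$n_region, c(0L, 400L))
})

test_that("size classification matches the published ranges", {
  expect_equal(classify_size(136), "S")
  expect_equal(classify_size(215), "S")
  expect_equal(classify_size(219), "intermediate")
  expect_equal(classify_size(230), "intermediate")
  expect_equal(classify_size(243), "L")
  expect_equal(classify_size(309), "L")
  expect_equal(classify_size(c(150, 250)), c("S", "L"))
  expect_error(classify_size(0), "positive")
})

test_that("group assignment counts RTX nonapeptides in the C region", {
  rtx <- "ALAGGAGDD"  # fits x-(L/I/F)-x-G-G-x-G-(N/D)-D
  mk <- function(n_rtx) {
    c_reg <- paste0(strrep("S", 50),
                    strrep(paste0(rtx, "TT"), n_rtx), strrep("S", 50))
    paste0(build_protein(200, list(strrep("L", 176)), 0), c_reg)
  }
  expect_equal(segment_modules(list(id = "p", seq = mk(3)))$group, "I")
  expect_equal(segment_modules(list(id = "p", seq = mk(0)))$group, "II")
  # a single hit stays below the default threshold of 2
  expect_equal(segment_modules(list(id = "p", seq = mk(1)))$group, "II")
  arch <- segment_modules(list(id = "p", seq = mk(3)))
  expect_equal(assign_group(arch), "I")
})

test_that("QC flags mark truncation, size anomalies, and missing DGDGD", {
  # protein starting mid-module: first boundary lands close to position 0
  trunc <- paste0(strrep("L", 50), "DDGP", strrep("V", 176), "DDGP",
                  strrep("S", 200))
  expect_true("starts_in_repeat" %in%
                qc_flags(segment_modules(list(id = "p", seq = trunc))))

  # DGDGD 15 aa upstream of the terminal motif start
  body <- paste0(strrep("L", 156), "DGDGD", strrep("L", 15))
  with_dg <- build_protein(200, list(body), 300)
  arch <- segment_modules(list(id = "p", seq = with_dg))
  expect_false("missing_dgdgd" %in% qc_flags(arch))
  expect_true(15L %in% arch$modules$dgdgd_offsets[[1]])

  no_dg <- build_protein(200, list(strrep("L", 176)), 300)
  expect_true("missing_dgdgd" %in%
                qc_flags(segment_modules(list(id = "p", seq = no_dg))))

  # 230-aa module sits in the S/L gap
  mid <- build_protein(200, list(strrep("L", 226)), 300)
  arch_mid <- segment_modules(list(id = "p", seq = mid))
  expect_equal(arch_mid$modules$size_class, "intermediate")
  expect_true("intermediate_size_module" %in% qc_flags(arch_mid))
})

test_that("a second unlinked module cluster is reported as a flag", {
  left <- build_protein(100, rep(list(strrep("L", 176)), 2), 0)
  right <- build_protein(404, rep(list(strrep("V", 176)), 2), 100,
                         n_char = "Q")
  arch <- segment_modules(list(id = "p", seq = paste0(left, right)))
  expect_equal(nrow(arch$modules), 2)
  expect_equal(arch$modules$start[1], 100L)  # leftmost chain wins the tie
  expect_true("extra_module_chain" %in% qc_flags(arch))
})

test_that("raising the minimum module length never increases the module count", {
  prot <- build_protein(200, list(strrep("L", 126), strrep("V", 176),
                                  strrep("I", 246)), 300)
  counts <- vapply(c(120L, 130L, 180L, 250L, 320L), function(mn) {
    nrow(segment_modules(list(id = "p", seq = prot),
                         ddxp_config(min_module_len = mn))$modules)
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[1], 3L)
})

test_that("simulated lineages are recovered exactly at mutation rate zero", {
  set.seed(202)
  for (rep in 1:10) {
    cfg <- sim_config(seed = sample.int(1e6, 1),
                      n_insertions = sample(1:3, 1),
                      amplification_copies = sample(1:4, 1),
                      mutation_rate = 0)
    lin <- simulate_lineage(cfg)
    arch <- segment_modules(lin$protein)
    expect_equal(arch$modules$start, lin$truth$modules$start)
    expect_equal(arch$modules$end, lin$truth$modules$end)
    # tiling invariant
    expect_equal(paste0(substr(lin$protein$seq, 1, arch$n_region[2]),
                        paste(arch$modules$seq, collapse = ""),
                        substr(lin$protein$seq, arch$c_region[1] + 1,
                               arch$c_region[2])),
                 lin$protein$seq)
  }
})

test_that("scan_proteins returns one row per module plus flagged empties", {
  seqs <- tibble::tibble(
    id = c("rich", "empty"),
    description = "",
    seq = c(build_protein(200, rep(list(strrep("L", 176)), 2), 300),
            strrep("A", 300)),
    alphabet = "protein")
  tbl <- scan_proteins(seqs)
  expect_equal(nrow(tbl), 3)
  expect_equal(sum(!is.na(tbl$module_index)), 2)
  expect_equal(tbl$qc_flags[tbl$protein_id == "empty"], "no_module_chain")
  archs <- attr(tbl, "architectures")
  expect_named(archs, c("rich", "empty"))
  g <- glance(archs$rich)
  expect_equal(g$n_modules, 2L)
  td <- tidy(archs$rich)
  expect_equal(td$segment, c("N", "module_1", "module_2", "C"))
})
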