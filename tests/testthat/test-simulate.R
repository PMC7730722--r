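test_that("ancestral genes carry exactly one planted target and nothing else", {
  set.seed(1)
  anc <- make_ancestral_gene(sim_config())
  hits <- scan_motif(anc$protein, motif_patterns()$DDXP)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$end, 206L)  # N region (200 aa) + 6-aa target peptide
  expect_true(validate_pairing(anc$protein, anc$cds, anc$pairing))
  target <- substr(anc$cds$seq, anc$target_site[1] + 1, anc$target_site[2])
  expect_true(iupac_match(target, tsd18_pattern()))
})

test_that("the phenylalanine bias controls the first target codon", {
  set.seed(2)
  for (i in 1:10) {
    anc <- make_ancestral_gene(sim_config(phe_bias = 1))
    c1 <- substr(anc$cds$seq, anc$target_site[1] + 1, anc$target_site[1] + 3)
    expect_true(c1 %in% c("TTC", "TTT"))
  }
  for (i in 1:10) {
    anc <- make_ancestral_gene(sim_config(phe_bias = 0))
    c1 <- substr(anc$cds$seq, anc$target_site[1] + 1, anc$target_site[1] + 3)
    expect_false(c1 %in% c("TTC", "TTT"))
  }
})

test_that("insertion duplicates the 18-bp target around the module body", {
  set.seed(3)
  anc <- make_ancestral_gene(sim_config())
  site <- anc$target_site[1]
  target <- substr(anc$cds$seq, site + 1, site + 18)
  body <- backtranslate(paste(sample(setdiff(AA20, "P"), 150, TRUE),
                              collapse = ""))
  ins <- simulate_insertion(anc$cds$seq, site, body)
  # both flanks equal the original target
  expect_equal(substr(ins$cds, site + 1, site + 18), target)
  right <- ins$tsd_spans$right
  expect_equal(substr(ins$cds, right[1] + 1, right[2]), target)
  expect_equal(right[2] - right[1], 18L)
  # module length is body/3 + 6 aa and ends with the terminal motif
  span <- ins$module_span
  expect_equal((span[2] - span[1]) / 3, nchar(body) / 3 + 6)
  prot <- sub("\\*$", "", translate_cds(ins$cds))
  arch <- segment_modules(list(id = "p", seq = prot))
  expect_equal(nrow(arch$modules), 1)
  expect_equal(arch$modules$start * 3L, span[1])
  expect_equal(arch$modules$end * 3L, span[2])

  # invalid requests are refused
  expect_error(simulate_insertion(anc$cds$seq, site + 1, body), "codon boundary")
  expect_error(simulate_insertion(anc$cds$seq, site + 3, body),
               "does not match")
  expect_error(simulate_insertion(anc$cds$seq, site, paste0(body, "A")),
               "divisible by 3")
  expect_error(simulate_insertion(anc$cds$seq, site, paste0(body, "TAA")),
               "stop codon")
  expect_error(simulate_insertion(anc$cds$seq, site,
                                  paste0(body, backtranslate("DDGP"))),
               "DDxP motif")
})

test_that("amplification multiplies module and flanking TSD head-to-tail", {
  lin <- simulate_lineage(sim_config(seed = 21, n_insertions = 1,
                                     amplification_copies = 1))
  mod <- c(lin$truth$modules$cds_start[1], lin$truth$modules$cds_end[1])
  L <- mod[2] - mod[1]
  before <- nchar(lin$cds$seq)

  amp <- simulate_amplification(lin$cds$seq, mod, 3)
  expect_equal(nchar(amp$cds), before + 2 * L)
  prot <- sub("\\*$", "", translate_cds(amp$cds))
  arch <- segment_modules(list(id = "p", seq = prot))
  expect_equal(nrow(arch$modules), 3)
  expect_equal(nchar(prot), nchar(lin$protein$seq) + 2 * L / 3)
  # 3 module-junction pairs but 4 distinct TSD copies overall
  ev <- detect_tsds(amp$cds, arch, cds_pairing("p", "c", 0))
  expect_equal(nrow(ev), 3)
  copies <- unique(c(ev$left_start, ev$right_start))
  expect_equal(length(copies), 4)
  expect_equal(ev$mismatches_between_copies, rep(0L, 3))

  ident <- simulate_amplification(lin$cds$seq, mod, 1)
  expect_equal(ident$cds, lin$cds$seq)
  expect_error(simulate_amplification(lin$cds$seq, c(-3, 30), 2),
               "invalid module span")
})

test_that("mutation is seed-reproducible with a binomial substitution count", {
  lin <- simulate_lineage(sim_config(seed = 33, n_insertions = 2,
                                     amplification_copies = 3))
  cds <- lin$cds$seq

  same <- simulate_mutation(cds, 0)
  expect_equal(same$cds, cds)
  expect_equal(length(same$positions), 0L)

  set.seed(5)
  m1 <- simulate_mutation(cds, 0.02)
  set.seed(5)
  m2 <- simulate_mutation(cds, 0.02)
  expect_equal(m1$cds, m2$cds)
  expect_equal(m1$positions, m2$positions)
  expect_false(m1$cds == cds)

  # count within 4 sigma of Binomial(n - 3, rate)
  n <- nchar(cds) - 3
  rate <- 0.05
  set.seed(6)
  k <- length(simulate_mutation(cds, rate)$positions)
  expect_lt(abs(k - n * rate), 4 * sqrt(n * rate * (1 - rate)))

  # no internal stops introduced, frame intact
  tr <- translate_cds(m1$cds)
  expect_false(grepl("\\*", sub("\\*$", "", tr)))
  expect_equal(nchar(m1$cds), nchar(cds))
})

test_that("lineages are deterministic per seed and frame-safe", {
  a <- simulate_lineage(sim_config(seed = 99))
  b <- simulate_lineage(sim_config(seed = 99))
  expect_identical(a$cds$seq, b$cds$seq)
  expect_identical(a$truth$modules, b$truth$modules)
  c_ <- simulate_lineage(sim_config(seed = 100))
  expect_false(identical(a$cds$seq, c_$cds$seq))

  for (s in c(4, 8, 15)) {
    lin <- simulate_lineage(sim_config(seed = s, n_insertions = 2,
                                       amplification_copies = 2,
                                       mutation_rate = 0.01))
    tr <- translate_cds(lin$cds$seq)
    expect_match(tr, "\\*$")
    expect_false(grepl("\\*", sub("\\*$", "", tr)))
    expect_equal(nchar(lin$protein$seq), (nchar(lin$cds$seq) - 3) / 3)
    expect_equal(lin$protein$seq, sub("\\*$", "", tr))
  }
})

test_that("insertion plus amplification yields the configured module count", {
  lin <- simulate_lineage(sim_config(seed = 71, n_insertions = 1,
                                     amplification_copies = 5))
  expect_equal(nrow(lin$truth$modules), 5)
  arch <- segment_modules(lin$protein)
  expect_equal(nrow(arch$modules), 5)
  expect_equal(arch$modules$start, lin$truth$modules$start)
  # every true module lies inside the protein and ends with the motif
  for (i in seq_len(nrow(lin$truth$modules))) {
    e <- lin$truth$modules$end[i]
    expect_equal(substr(lin$protein$seq, e - 3, e),
                 arch$modules$terminal_motif[i])
  }
  # module bodies carry a DGDGD motif within the documented window
  expect_false("missing_dgdgd" %in% qc_flags(arch))
})

test_that("a lineage without insertions is an empty (rep-) protein", {
  lin <- simulate_lineage(sim_config(seed = 13, n_insertions = 0))
  expect_equal(nrow(lin$truth$modules), 0)
  arch <- segment_modules(lin$protein)
  expect_equal(nrow(arch$modules), 0)
  expect_equal(qc_flags(arch), "no_module_chain")
})

test_that("every simulated TSD is exactly 18 bp and consensus-conforming", {
  set.seed(303)
  for (s in sample.int(1e6, 5)) {
    lin <- simulate_lineage(sim_config(seed = s, n_insertions = 2,
                                       amplification_copies = 2))
    t <- lin$truth$tsds
    expect_true(all(t$left_end - t$left_start == 18L))
    expect_true(all(t$right_end - t$right_start == 18L))
    for (i in seq_len(nrow(t))) {
      l <- substr(lin$cds$seq, t$left_start[i] + 1, t$left_end[i])
      r <- substr(lin$cds$seq, t$right_start[i] + 1, t$right_end[i])
      expect_equal(l, r)
      expect_true(iupac_match(l, tsd18_pattern()))
    }
  }
})
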