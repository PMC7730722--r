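# Independent oracles and fixture builders. These deliberately avoid the
# code paths they check: scanning by explicit sliding window, clustering
# by transitive closure on the identity matrix, UPGMA by a naive
# size-weighted agglomeration that records cophenetic distances directly.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# all match start positions (0-based) of a motif pattern, by brute force
oracle_scan_starts <- function(seq, pattern) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1]]
  k <- length(pattern$elements)
  allowed <- lapply(pattern$elements, function(el) {
    if (pattern$alphabet == "dna") {
      iupac_expand(el)
    } else if (nchar(el) == 0) {
      LETTERS
    } else {
      strsplit(el, "")[[1]]
    }
  })
  starts <- integer(0)
  if (nchar(seq) < k) return(starts)
  for (s in 0:(nchar(seq) - k)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      if (!chars[s + j] %in% allowed[[j]]) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# transitive closure of the "same type" relation; returns component label
# per item, numbered by first appearance
oracle_cluster_labels <- function(idm, threshold) {
  n <- nrow(idm)
  adj <- idm > threshold | idm == 1
  diag(adj) <- TRUE
  repeat {
    nxt <- (adj %*% adj) > 0
    if (all(nxt == adj)) break
    adj <- nxt
  }
  comp <- apply(adj, 1, function(r) min(which(r)))
  match(comp, unique(comp))
}

# UPGMA cophenetic matrix by direct agglomeration (n small)
oracle_upgma_cophenetic <- function(d) {
  n <- nrow(d)
  labs <- rownames(d)
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  members <- lapply(seq_len(n), identity)
  D <- d
  while (length(members) > 1) {
    m <- length(members)
    bv <- Inf
    bi <- bj <- NA
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        if (D[i, j] < bv) {
          bv <- D[i, j]
          bi <- i
          bj <- j
        }
      }
    }
    for (a in members[[bi]]) {
      for (b in members[[bj]]) {
        coph[a, b] <- coph[b, a] <- bv
      }
    }
    ni <- length(members[[bi]])
    nj <- length(members[[bj]])
    keep <- setdiff(seq_len(m), c(bi, bj))
    if (length(keep) > 0) {
      kept <- D[keep, keep, drop = FALSE]
      merged_row <- (ni * D[bi, keep] + nj * D[bj, keep]) / (ni + nj)
      newD <- rbind(cbind(kept, merged_row, deparse.level = 0),
                    c(merged_row, 0))
    } else {
      newD <- matrix(0, 1, 1)
    }
    members <- c(members[keep], list(c(members[[bi]], members[[bj]])))
    D <- newD
  }
  coph
}

# synonymous-codon table (bacterial code) for building silent mutations
codons_by_aa_for_tests <- function() {
  gc11 <- Biostrings::getGeneticCode("11")
  split(names(gc11), unname(gc11))
}

random_aa_string <- function(n) paste(sample(AA20, n, replace = TRUE),
                                      collapse = "")

random_dna_string <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                              replace = TRUE), collapse = "")

# one random 18-mer conforming to the recognition consensus
random_tsd18 <- function() {
  p <- tsd18_pattern()
  paste(vapply(p$elements, function(el) sample(iupac_expand(el), 1),
               character(1)), collapse = "")
}

# protein built from explicit N / module / C pieces; pieces use disjoint
# residue alphabets so no spurious terminal motifs arise
build_protein <- function(n_len, module_bodies, c_len,
                          terminal = "DDGP", n_char = "A", c_char = "S") {
  paste0(strrep(n_char, n_len - 4L), terminal,
         paste(vapply(module_bodies, function(b) paste0(b, terminal),
                      character(1)), collapse = ""),
         strrep(c_char, c_len))
}
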