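# window enumeration and the mismatch-tolerant scan

test_that("window enumeration slides one step at a time, both orientations", {
  set.seed(11)
  rna <- list(rna_id = "r", sequence = rand_dna(100))
  w <- enumerate_windows(rna)
  expect_identical(sum(w$orientation == "sense"), 80L)   # L - k + 1
  expect_identical(sum(w$orientation == "antisense"), 80L)
  expect_identical(w$start[w$orientation == "sense"], 0:79)
  s5 <- w$bases[w$orientation == "sense" & w$start == 5]
  expect_identical(s5, substr(rna$sequence, 6, 26))
  a5 <- w$bases[w$orientation == "antisense" & w$start == 5]
  expect_identical(a5, revcomp_chr(s5))
  expect_false(any(w$short_molecule))

  w21 <- enumerate_windows(list(rna_id = "r", sequence = rand_dna(21)))
  expect_identical(nrow(w21), 2L)

  w19 <- enumerate_windows(list(rna_id = "r", sequence = rand_dna(19)))
  expect_identical(nrow(w19), 2L)
  expect_true(all(w19$short_molecule))
  expect_identical(nchar(w19$bases), c(19L, 19L))

  expect_identical(nrow(enumerate_windows(rna, include_antisense = FALSE)),
                   80L)
  expect_error(enumerate_windows(rna, k = 0), "positive")
})

test_that("mismatch counting honors the ambiguity policy", {
  expect_identical(count_mismatches("ACGTACGTACGTACGTACGTA",
                                    "ACGTACGTACGTACGTACGTA"), 0L)
  expect_identical(count_mismatches("ACGTA", "ACCTA"), 1L)
  expect_identical(count_mismatches("acgta", "ACGTA"), 0L)  # case-insensitive
  expect_identical(count_mismatches("NACGT", "AACGT"), 1L)  # strict: N always
  expect_identical(count_mismatches("NACGT", "NACGT"), 1L)  # even N vs N
  expect_identical(count_mismatches("NACGT", "AACGT", "iupac"), 0L)
  expect_identical(count_mismatches("RACGT", "GACGT", "iupac"), 0L)  # R = A/G
  expect_identical(count_mismatches("RACGT", "CACGT", "iupac"), 1L)
  expect_error(count_mismatches("ACG", "ACGT"), "equal length")
})

test_that("seed-region test looks at window positions 2-8 only", {
  w <- "ACGTACGTACGTACGTACGTA"
  expect_true(seed_perfect(w, w))
  s <- w
  substr(s, 15, 15) <- if (substr(s, 15, 15) == "A") "C" else "A"
  substr(s, 20, 20) <- if (substr(s, 20, 20) == "A") "C" else "A"
  expect_true(seed_perfect(w, s))       # mismatches outside the seed
  s5 <- w
  substr(s5, 5, 5) <- if (substr(s5, 5, 5) == "A") "C" else "A"
  expect_false(seed_perfect(w, s5))     # mismatch at position 5
  expect_warning(res <- seed_perfect("ACGTA", "ACGTA"), "8 nt")
  expect_false(res)
})

test_that("scan recovers planted homologies at the right identity class", {
  set.seed(21)
  rna_seq <- rand_dna(60)
  gene <- rand_dna(120)
  # verbatim 21-mer, sense
  p0 <- plant_window(gene, rna_seq, rna_start0 = 10, gene_pos0 = 40, "+", 0)
  gs <- tiny_gene_set(list(g1 = p0$gene_seq))
  reg <- tiny_registry(list(r1 = rna_seq))
  hits <- scan_gene_set(reg[1, ], gs)
  planted <- hits[hits$rna_window_start == 10 & hits$strand == "+" &
                    hits$gene_position == 40, ]
  expect_identical(nrow(planted), 1L)
  expect_identical(planted$mismatches, 0L)
  expect_identical(planted$identity_class, 21L)
  expect_true(planted$seed_perfect)

  # two substitutions -> 19/21
  set.seed(22)
  p2 <- plant_window(gene, rna_seq, 10, 40, "+", 2)
  h2 <- scan_gene_set(reg[1, ], tiny_gene_set(list(g1 = p2$gene_seq)))
  planted2 <- h2[h2$rna_window_start == 10 & h2$strand == "+" &
                   h2$gene_position == 40, ]
  expect_identical(planted2$mismatches, 2L)
  expect_identical(planted2$identity_class, 19L)

  # three substitutions -> below threshold, no hit at that locus
  set.seed(23)
  p3 <- plant_window(gene, rna_seq, 10, 40, "+", 3)
  h3 <- scan_gene_set(reg[1, ], tiny_gene_set(list(g1 = p3$gene_seq)))
  expect_identical(nrow(h3[h3$rna_window_start == 10 & h3$strand == "+" &
                             h3$gene_position == 40, ]), 0L)

  # reverse-complement plant -> strand '-'
  pm <- plant_window(gene, rna_seq, 25, 60, "-", 0)
  hm <- scan_gene_set(reg[1, ], tiny_gene_set(list(g1 = pm$gene_seq)))
  plantedm <- hm[hm$rna_window_start == 25 & hm$gene_position == 60, ]
  expect_true("-" %in% plantedm$strand)
  expect_identical(plantedm$mismatches[plantedm$strand == "-"], 0L)
})

test_that("scan equals the brute-force oracle on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n_genes <- sample(2:4, 1)
    gseqs <- vapply(sample(120:250, n_genes, replace = TRUE), rand_dna, "")
    rna_seq <- rand_dna(sample(25:90, 1))
    if (i %% 2 == 0) {   # plant something so non-empty cases are exercised
      g <- sample(n_genes, 1)
      pl <- plant_window(gseqs[g], rna_seq,
                         sample(0:max(nchar(rna_seq) - 21, 0), 1),
                         sample(0:(nchar(gseqs[g]) - 21), 1),
                         sample(c("+", "-"), 1), sample(0:2, 1))
      gseqs[g] <- pl$gene_seq
    }
    ids <- paste0("g", seq_len(n_genes))
    gs <- tiny_gene_set(setNames(as.list(gseqs), ids))
    reg <- tiny_registry(list(r1 = rna_seq))
    got <- scan_gene_set(reg[1, ], gs)
    want <- oracle_scan(rna_seq, gseqs)
    expect_identical(hit_keys(got), hit_keys(want, ids))
  }
})

test_that("identity class plus mismatches is 21 for full-length windows", {
  set.seed(32)
  rna_seq <- rand_dna(80)
  gene <- rand_dna(200)
  for (m in 0:2) {
    p <- plant_window(gene, rna_seq, 4 + m, 30 + 30 * m, "+", m)
    gene <- p$gene_seq
  }
  hits <- scan_gene_set(tiny_registry(list(r = rna_seq))[1, ],
                        tiny_gene_set(list(g = gene)))
  expect_gt(nrow(hits), 0)
  expect_true(all(hits$identity_class + hits$mismatches == 21L))
  expect_true(all(hits$identity_class %in% 19:21))
})

test_that("scanning an RNA and its reverse complement give mirrored hits", {
  set.seed(33)
  gene <- rand_dna(300)
  rna_seq <- rand_dna(70)
  p1 <- plant_window(gene, rna_seq, 12, 100, "+", 1)
  p2 <- plant_window(p1$gene_seq, rna_seq, 40, 200, "-", 0)
  gs <- tiny_gene_set(list(g = p2$gene_seq))
  fwd <- scan_gene_set(tiny_registry(list(r = rna_seq))[1, ], gs)
  rev <- scan_gene_set(tiny_registry(list(r = revcomp_chr(rna_seq)))[1, ], gs)
  # same per-gene multiset of (position, mismatches); window coordinates remap
  expect_identical(sort(paste(fwd$gene_position, fwd$mismatches)),
                   sort(paste(rev$gene_position, rev$mismatches)))
})

test_that("a prefix of an RNA never yields more hits than the full RNA", {
  set.seed(34)
  gene <- rand_dna(400)
  rna_seq <- rand_dna(120)
  for (s in c(5, 40, 70)) {
    p <- plant_window(gene, rna_seq, s, 50 + 2 * s, "+", sample(0:2, 1))
    gene <- p$gene_seq
  }
  gs <- tiny_gene_set(list(g = gene))
  full <- scan_gene_set(tiny_registry(list(r = rna_seq))[1, ], gs)
  for (cut in c(30, 60, 90)) {
    pre <- scan_gene_set(
      tiny_registry(list(r = substr(rna_seq, 1, cut)))[1, ], gs)
    expect_lte(nrow(pre), nrow(full))
  }
})

test_that("short siRNAs are matched full length on the over-21 scale", {
  set.seed(35)
  si <- rand_dna(19)
  gene <- rand_dna(100)
  substr(gene, 31, 49) <- si   # perfect 19-nt plant
  gs <- tiny_gene_set(list(g = gene))
  reg <- tiny_registry(list(s1 = si), molecule_class = "siRNA")
  hits <- scan_gene_set(reg[1, ], gs)
  planted <- hits[hits$gene_position == 30 & hits$strand == "+", ]
  expect_identical(planted$mismatches, 0L)
  expect_identical(planted$identity_class, 19L)   # 19 matched nt over 21

  # one substitution on a 19-mer falls below the lowest class: no hit
  gene1 <- gene
  substr(gene1, 35, 35) <- setdiff(c("A", "C", "G", "T"),
                                   substr(gene1, 35, 35))[1]
  h1 <- scan_gene_set(reg[1, ], tiny_gene_set(list(g = gene1)))
  expect_identical(nrow(h1[h1$gene_position == 30 & h1$strand == "+", ]), 0L)

  # a 20-mer tolerates one substitution (identity 19)
  si20 <- rand_dna(20)
  gene2 <- rand_dna(100)
  substr(gene2, 41, 60) <- si20
  substr(gene2, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                   substr(gene2, 50, 50))[1]
  reg20 <- tiny_registry(list(s2 = si20), molecule_class = "siRNA")
  h20 <- scan_gene_set(reg20[1, ], tiny_gene_set(list(g = gene2)))
  planted20 <- h20[h20$gene_position == 40 & h20$strand == "+", ]
  expect_identical(planted20$mismatches, 1L)
  expect_identical(planted20$identity_class, 19L)
})

test_that("excluded and sequence-less genes are never searched", {
  set.seed(36)
  rna_seq <- rand_dna(60)
  gene <- plant_window(rand_dna(100), rna_seq, 10, 30, "+", 0)$gene_seq
  reg <- tiny_registry(list(r = rna_seq))
  for (flag in c("low_quality", "unknown_function", "unannotated")) {
    gs <- tiny_gene_set(list(g1 = gene, g2 = rand_dna(100)),
                        quality = c(flag, "normal"))
    hits <- scan_gene_set(reg[1, ], gs)
    expect_false("g1" %in% hits$gene_id)
  }
  # the same gene searched when normal
  gs_ok <- tiny_gene_set(list(g1 = gene))
  expect_true("g1" %in% scan_gene_set(reg[1, ], gs_ok)$gene_id)
  # zero-sequence gene skipped with a message
  gs0 <- gene_set(data.frame(gene_id = c("g1", "g0"), gene_name = "x",
                             functional_group = "other",
                             quality_flag = "normal", ortholog_of = "",
                             stringsAsFactors = FALSE),
                  list(g1 = gene, g0 = character(0)))
  expect_message(h0 <- scan_gene_set(reg[1, ], gs0), "zero sequences")
  expect_false("g0" %in% h0$gene_id)
})

test_that("ambiguous bases never match under the strict policy", {
  rna_seq <- paste(rep("ACGTA", 5), collapse = "")  # 25 nt
  gene <- paste0(rand_dna(20), substr(rna_seq, 1, 21), rand_dna(20))
  gene_n <- gene
  substr(gene_n, 25, 25) <- "N"
  substr(gene_n, 30, 30) <- "N"
  substr(gene_n, 35, 35) <- "N"   # three Ns inside the planted region
  gs <- tiny_gene_set(list(g = gene_n))
  hits <- scan_gene_set(tiny_registry(list(r = rna_seq))[1, ], gs)
  expect_identical(nrow(hits[hits$rna_window_start == 0 & hits$strand == "+" &
                               hits$gene_position == 20, ]), 0L)
  # with only two Ns the hit survives at 19/21
  gene_2n <- gene
  substr(gene_2n, 25, 25) <- "N"
  substr(gene_2n, 30, 30) <- "N"
  h2 <- scan_gene_set(tiny_registry(list(r = rna_seq))[1, ],
                      tiny_gene_set(list(g = gene_2n)))
  at <- h2[h2$rna_window_start == 0 & h2$strand == "+" &
             h2$gene_position == 20, ]
  expect_identical(at$mismatches, 2L)
})
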