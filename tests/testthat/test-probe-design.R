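test_that("candidate enumeration counts windows and excludes homotetramers", {
  expect_equal(nrow(enumerate_candidates("ACGTACGTACGTACGTACGTACGTA")), 1L)
  ## a 25-mer whose only flaw is a homotetramer yields nothing
  expect_equal(nrow(enumerate_candidates("ACGTACGTACGTACGTACGTCCCCA")), 0L)
  s30 <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  expect_equal(nrow(enumerate_candidates(s30)), 6L)   # 30 - 25 + 1
  ## every window covering the GGGG run is excluded
  s <- paste0(random_dna(40, seed = 2), "AGGGGA", random_dna(40, seed = 3))
  cand <- enumerate_candidates(s)
  covered <- vapply(cand$target, function(w) grepl("GGGG|CCCC", w),
                    logical(1))
  expect_false(any(covered))
  ## count agrees with a direct grepl scan over all windows
  n <- nchar(s)
  all_win <- substring(s, 1:(n - 24), 25:n)
  expect_equal(nrow(cand), sum(!grepl("GGGG|CCCC", all_win)))
  ## legacy mode keeps CCCC windows
  sc <- paste0(random_dna(30, seed = 4), "CCCC", random_dna(30, seed = 5))
  winc <- substring(sc, 1:(nchar(sc) - 24), 25:nchar(sc))
  expect_equal(nrow(enumerate_candidates(sc, legacy_g_filter = TRUE)),
               sum(!grepl("GGGG", winc)))
})

test_that("enumeration count matches the combinatorial oracle on random sequences", {
  set.seed(10)
  for (rep in 1:20) {
    s <- random_dna(sample(60:300, 1))
    n <- nchar(s)
    wins <- substring(s, 1:(n - 24), 25:n)
    expect_equal(nrow(enumerate_candidates(s)), sum(!grepl("GGGG|CCCC", wins)))
  }
})

test_that("short transcripts yield an empty candidate list with a warning", {
  expect_warning(cand <- enumerate_candidates(random_dna(20, seed = 6)))
  expect_equal(nrow(cand), 0L)
})

test_that("arm splitting is antiparallel-correct for every split position", {
  t25 <- random_dna(25, seed = 7)
  for (a5 in 2:22) {
    s <- split_arms(t25, a5)
    expect_equal(nchar(s$arm5), a5)
    expect_equal(nchar(s$arm5) + nchar(s$arm3), 25L)
    expect_equal(s$arm5, revcomp(substr(t25, 1, a5)))
    expect_equal(s$arm3, revcomp(substr(t25, a5 + 1, 25)))
  }
  ## poly-A target gives poly-T arms
  s <- split_arms(strrep("A", 25))
  expect_equal(s$arm5, strrep("T", 18))
  expect_equal(s$arm3, strrep("T", 7))
  expect_error(split_arms(t25, 0))
  expect_error(split_arms(t25, 25))
})

test_that("junction classes follow the default efficiency table", {
  expect_equal(junction_quality("TG"), "disfavored")
  expect_equal(junction_quality("CG"), "disfavored")
  expect_equal(junction_quality("GA"), "disfavored")
  expect_equal(junction_quality("TC"), "favored")
  expect_equal(junction_quality("CC"), "favored")
  expect_equal(junction_quality("AC"), "favored")
  expect_equal(junction_quality("AT"), "neutral")
  ## every junction containing G is disfavored
  tab <- default_junction_table()
  expect_true(all(tab[grepl("G", names(tab))] == "disfavored"))
  expect_equal(length(tab), 16L)
  ## user override
  tab["TG"] <- "favored"
  expect_equal(junction_quality("TG", tab), "favored")
})

test_that("off-target screen fails exact copies and honours the boundary", {
  tr <- make_transcriptome(n_genes = 10, length_range = c(200, 400),
                           seed = 20)$transcripts
  cand <- substr(tr$sequence[1], 10, 34)
  ## plant an exact copy in another gene
  tr2 <- tr
  substr(tr2$sequence[5], 50, 74) <- cand
  sc <- offtarget_screen(cand, tr$gene_id[1], tr2)
  expect_false(sc$pass)
  expect_equal(sc$min_mm, 0L)
  ## planted distance 5 fails, distance 6 passes
  for (mm in c(5L, 6L)) {
    tx <- make_transcriptome(n_genes = 12, length_range = c(300, 500),
                             n_homolog_pairs = 1, homolog_mismatches = mm,
                             seed = 21)
    th <- tx$truth[1, ]
    src <- tx$transcripts[tx$transcripts$gene_id == th$source_gene, ]
    w <- substr(src$sequence, th$source_start + 1, th$source_start + 25)
    r <- offtarget_screen(w, th$source_gene, tx$transcripts)
    expect_equal(r$min_mm, mm)
    expect_equal(r$pass, mm >= 6L)
  }
  ## empty reference: pass with infinite distance
  e <- offtarget_screen(cand, tr$gene_id[1],
                        tr[tr$gene_id == tr$gene_id[1], ])
  expect_true(e$pass)
  expect_equal(e$min_mm, Inf)
})

test_that("off-target verdicts match the exhaustive alignment oracle", {
  tr <- make_transcriptome(n_genes = 15, length_range = c(200, 500),
                           seed = 22)$transcripts
  set.seed(23)
  for (i in 1:25) {
    g <- sample(nrow(tr), 1)
    s <- sample(nchar(tr$sequence[g]) - 24, 1)
    cand <- substr(tr$sequence[g], s, s + 24)
    mine <- offtarget_screen(cand, tr$gene_id[g], tr)
    expect_equal(mine$min_mm, oracle_min_mm(cand, tr$gene_id[g], tr))
  }
})

test_that("structure scoring detects hairpins and is revcomp-symmetric", {
  expect_equal(structure_score(strrep("A", 60)), 0)
  ## 20-bp GC stem with 20-nt loop: 20 pairs * -3 + 19 stacks * -1
  hp <- paste0(strrep("GC", 10), strrep("A", 20),
               revcomp(strrep("GC", 10)))
  expect_equal(structure_score(hp), -79)
  ## shuffled control has strictly less structure
  set.seed(30)
  shuf <- paste(sample(strsplit(hp, "")[[1]]), collapse = "")
  expect_lt(structure_score(hp), structure_score(shuf))
  ## symmetry under reverse complement
  for (i in 1:5) {
    s <- random_dna(40)
    expect_equal(structure_score(s), structure_score(revcomp(s)))
  }
  expect_error(structure_score("ACGT", backend = "bogus"))
})

test_that("ranking keeps the least structured probes with coordinate tie-break", {
  cand <- data.frame(start = c(5L, 1L, 9L, 3L),
                     structure_dG = c(-10, -2, -2, -7))
  sel <- rank_and_select(cand, n = 10)
  expect_equal(nrow(sel), 4L)                  # fewer than n: all returned
  expect_equal(sel$start, c(1L, 9L, 3L, 5L))   # tie at -2 by coordinate
  expect_equal(sel$rank, 1:4)
  sel2 <- rank_and_select(cand, n = 2)
  expect_equal(nrow(sel2), 2L)
  ## deterministic under input shuffling
  set.seed(31)
  big <- data.frame(start = sample(1:100, 15),
                    structure_dG = sample(c(-5, -9, -12), 15, replace = TRUE))
  a <- rank_and_select(big, n = 10)
  b <- rank_and_select(big[sample(15), ], n = 10)
  expect_equal(a, b)
  expect_equal(nrow(a), 10L)
})

test_that("probe assembly layout holds over random parts", {
  set.seed(32)
  for (i in 1:1000) {
    t25 <- random_dna(25)
    a5 <- sample(2:22, 1)
    arms <- split_arms(t25, a5)
    bc <- random_dna(8)
    anchor <- random_dna(23)
    p <- assemble_probe(arms$arm5, arms$arm3, anchor, barcode8 = bc)
    expect_equal(nchar(p), 60L)
    expect_equal(substr(p, a5 + 1, a5 + 4), substr(bc, 5, 8))
    expect_equal(substr(p, 1, a5), arms$arm5)
    expect_equal(substr(p, 61 - (25 - a5), 60), arms$arm3)
  }
  ## singleplex: 35-nt filler linker, still 60 nt
  arms <- split_arms(random_dna(25), 18)
  ps <- assemble_probe(arms$arm5, arms$arm3, fillers = c("TATTAT", "ATTATA"))
  expect_equal(nchar(ps), 60L)
  expect_error(assemble_probe(arms$arm5, arms$arm3, anchor = "ACGT",
                              barcode8 = random_dna(8)))
  expect_error(assemble_probe(arms$arm5, arms$arm3, barcode8 = "ACGT"))
})

test_that("design pipeline emits ranked, filtered, 60-nt probes", {
  tx <- make_transcriptome(n_genes = 8, length_range = c(300, 500),
                           seed = 40)
  tr <- tx$transcripts
  code <- assign_barcodes(generate_code(8, 3, n_needed = 10),
                          tr$gene_id)
  pr <- design_probes(tr[1:2, ], tr, assignment = code$assignment,
                      n_per_gene = 5)
  expect_true(nrow(pr) > 0)
  expect_true(all(nchar(pr$probe_seq) == 60L))
  expect_true(all(pr$offtarget_min_mm >= 6))
  expect_false(any(junction_quality(pr$junction[1]) == "disfavored"))
  expect_true(all(pr$rank <= 5))
  ## arms reverse-complement their sub-windows
  for (i in seq_len(nrow(pr))) {
    expect_equal(pr$arm5[i], revcomp(substr(pr$target[i], 1, 18)))
    expect_equal(pr$arm3[i], revcomp(substr(pr$target[i], 19, 25)))
  }
})

test_that("short targets use the whole sequence with a 3' arm of at least 7 nt", {
  mir <- data.frame(transcript_id = "mir1", gene_id = "mir1",
                    sequence = random_dna(21, seed = 41))
  ref <- make_transcriptome(n_genes = 5, length_range = c(200, 300),
                            seed = 42)$transcripts
  code <- assign_barcodes(generate_code(8, 3, n_needed = 6),
                          c(ref$gene_id, "mir1"))
  pr <- design_probes(mir, ref, assignment = code$assignment)
  expect_equal(nrow(pr), 1L)
  expect_gte(nchar(pr$arm3), 7L)
  expect_equal(nchar(pr$arm5) + nchar(pr$arm3), 21L)
  expect_equal(nchar(pr$probe_seq), 21L + 4L + 23L + 8L)
  expect_false(junction_quality(pr$junction) == "disfavored")
})

test_that("order sheets round-trip and lay out 96-well plates row-major", {
  tx <- make_transcriptome(n_genes = 2, length_range = c(400, 400),
                           seed = 43)$transcripts
  probes <- data.frame(transcript_id = rep("T", 96), rank = 1:96,
                       probe_seq = replicate(96, random_dna(60)))
  p <- tempfile(fileext = ".tsv")
  sheet <- write_order_sheet(probes, p)
  back <- read_order_sheet(p)
  expect_equal(nrow(back), 96L)
  expect_equal(back$sequence, probes$probe_seq)
  expect_equal(sheet$well[1], "A1")
  expect_equal(sheet$well[96], "H12")
  expect_equal(sheet$well[13], "B1")
  expect_error(write_order_sheet(probes[0, ], p))
})
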