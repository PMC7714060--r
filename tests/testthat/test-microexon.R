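# Helper: a one-gene model whose representative transcript has the given
# exon CDS lengths (all coding, plus-strand, contiguous layout with introns),
# so micro-exon calling can be exercised without files.
gene_from_exon_lens <- function(lens, utr5 = 0L, utr3 = 0L) {
  k <- length(lens)
  introns <- rep(100L, max(0L, k - 1L))
  glens <- lens + c(utr5, rep(0L, k - 1L)) + c(rep(0L, k - 1L), utr3)
  starts <- 10L + c(0L, cumsum(glens[-k] + introns))
  ends <- starts + glens
  cds_start <- starts + c(utr5, rep(0L, k - 1L))
  cds_end <- ends - c(rep(0L, k - 1L), utr3)
  tx <- make_transcript(exons = iv(starts, ends), cds = iv(cds_start, cds_end))
  tx$protein <- strrep("P", sum(lens) %/% 3L)
  list(id = "g1", transcripts = list(t1 = tx), representative = "t1")
}

test_that("micro-exon calling respects the coding-length threshold boundary", {
  g51 <- gene_from_exon_lens(c(100L, 51L, 149L))
  m <- call_microexons(g51)
  expect_identical(nrow(m), 1L)
  expect_identical(m$coding_length, 51L)
  expect_identical(m$exon_index, 1L)

  g52 <- gene_from_exon_lens(c(100L, 52L, 148L))
  expect_identical(nrow(call_microexons(g52)), 0L)

  # CDS portion, not full exon length, is what counts: 30 nt CDS + 40 nt UTR
  gutr <- gene_from_exon_lens(c(90L, 30L), utr3 = 40L)
  mu <- call_microexons(gutr)
  expect_identical(mu$coding_length, 30L)
  expect_identical(mu$end - mu$start, 30L)  # genomic record covers CDS part only
})

test_that("micro-exon CDS offsets and residues are consistent", {
  g <- gene_from_exon_lens(c(100L, 26L, 174L))
  m <- call_microexons(g)
  expect_identical(m$cds_end - m$cds_start, m$coding_length)
  expect_identical(m$cds_start, 100L)
  # residues [33, 42): 26 nt starting at nt 100 cuts the first codon only
  expect_identical(c(m$res_start, m$res_end), c(33L, 42L))
  expect_true(m$start_partial)
  expect_false(m$end_partial)
})

test_that("domain assignment takes the largest overlap, N-terminal on ties", {
  g <- gene_from_exon_lens(c(100L, 9L, 191L))
  m <- call_microexons(g)  # residues [33, 37)
  hits <- data.frame(protein_id = "t1", accession = "PF00847",
                     label = "AP2", start = c(0L, 35L), end = c(35L, 90L),
                     repeat_label = c("R1", "R2"), stringsAsFactors = FALSE)
  a <- assign_domain(m, hits)
  expect_identical(a$domain_label, "AP2/R1")  # equal 2-residue overlaps, N-terminal wins

  # 1-residue overlap is enough at the default min_overlap_aa
  hits1 <- data.frame(protein_id = "t1", accession = "PF01486",
                      label = "K-box", start = 0L, end = 34L,
                      repeat_label = "R1", stringsAsFactors = FALSE)
  expect_identical(assign_domain(m, hits1)$domain_label, "K-box")
  expect_identical(assign_domain(m, hits1, min_overlap_aa = 2L)$domain_label,
                   "none")

  # equal overlaps -> N-terminal-most hit
  hits2 <- data.frame(protein_id = "t1", accession = c("PF00319", "PF01486"),
                      label = c("SRF-TF", "K-box"), start = c(0L, 35L),
                      end = c(35L, 90L), repeat_label = c("R1", "R1"),
                      stringsAsFactors = FALSE)
  expect_identical(assign_domain(m, hits2)$domain_label, "MADS-box")

  # no hits on the protein
  expect_identical(assign_domain(m, hits[0, ])$domain_label, "none")
})

test_that("type classification matches domain context and exact length", {
  mk <- function(label, len) {
    r <- mexscan:::empty_microexon_frame()[NA_integer_, ]
    r$gene_id <- "g"; r$coding_length <- len; r$domain_label <- label
    r$res_start <- 10L; r$res_end <- 14L
    r$domain_start <- 0L; r$domain_end <- 60L
    r
  }
  expect_identical(classify_type(mk("AP2/R1", 9L))$type_label, "R1M1")
  expect_identical(classify_type(mk("AP2/R1", 26L))$type_label, "R1M2")
  expect_identical(classify_type(mk("AP2/R1", 31L))$type_label, "R1M3")
  expect_identical(classify_type(mk("AP2/R2", 45L))$type_label, "R2M1")
  # 9 nt in R2 is not a named class
  expect_identical(classify_type(mk("AP2/R2", 9L))$type_label, "unclassified")
  # ambiguous configuration is an error
  cfg <- rbind(default_type_config(),
               data.frame(name = "dup", context = "AP2/R1", length_nt = 9L,
                          position = "any"))
  expect_error(classify_type(mk("AP2/R1", 9L), cfg), "ambiguous")
})

test_that("tandem detection finds maximal consecutive runs and labels K-box pairs", {
  mk <- function(idx, label = "K-box") {
    r <- mexscan:::empty_microexon_frame()[NA_integer_, ]
    r$gene_id <- "g"; r$transcript_id <- "t1"; r$exon_index <- idx
    r$domain_label <- label; r$type_label <- "unclassified"
    r
  }
  # consecutive pair -> M1, M2
  m <- detect_tandem(rbind(mk(4L), mk(5L)))
  expect_identical(m$tandem_group, c("T1", "T1"))
  expect_identical(m$type_label, c("M1", "M2"))
  # interleaved long exon breaks the run
  m2 <- detect_tandem(rbind(mk(2L), mk(4L)))
  expect_true(all(is.na(m2$tandem_group)))
  # run of three in one group
  m3 <- detect_tandem(rbind(mk(4L), mk(5L), mk(6L)))
  expect_identical(unique(m3$tandem_group), "T1")
  expect_identical(m3$type_label, c("M1", "M2", "M3"))
  # AP2-context tandems keep their type labels
  m4 <- detect_tandem(rbind(mk(3L, "AP2/R1"), mk(4L, "AP2/R1")))
  expect_identical(m4$tandem_group, c("T1", "T1"))
  expect_identical(m4$type_label, c("unclassified", "unclassified"))
})

test_that("overlap summary computes per-family fractions with the family denominator", {
  fam <- data.frame(gene_id = c("a", "b", "m"),
                    family = c("AP2/ERF", "AP2/ERF", "MIKC"),
                    stringsAsFactors = FALSE)
  mk <- function(gene, label) {
    r <- mexscan:::empty_microexon_frame()[NA_integer_, ]
    r$gene_id <- gene; r$domain_label <- label
    r
  }
  micros <- rbind(mk("a", "AP2/R1"), mk("a", "AP2/R2"), mk("a", "none"),
                  mk("b", "AP2/R1"), mk("b", "AP2/R1"), mk("b", "AP2/R1"),
                  mk("b", "AP2/R2"), mk("b", "none"), mk("b", "none"),
                  mk("b", "none"), mk("m", "K-box"), mk("m", "none"))
  s <- summarize_overlap(micros, fam)
  expect_equal(s$fraction[s$group == "AP2/ERF"], 0.6)  # 6 of 10
  expect_equal(s$fraction[s$group == "MIKC"], 0.5)
  expect_equal(s$n_microexons[s$group == "all"], 12)
  # all unassigned -> 0, empty family -> missing
  s0 <- summarize_overlap(rbind(mk("a", "none")), fam)
  expect_equal(s0$fraction[s0$group == "AP2/ERF"], 0)
  expect_true(is.na(s0$fraction[s0$group == "MIKC"]))
})

test_that("summaries are invariant to gene order and strand mirroring", {
  cfg_p <- synthetic_config(seed = 7, n_genes = c(ap2 = 4L, mikc = 3L),
                            strand = "plus", extra_isoforms = FALSE)
  cfg_m <- synthetic_config(seed = 7, n_genes = c(ap2 = 4L, mikc = 3L),
                            strand = "minus", extra_isoforms = FALSE)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_genome(cfg_p, d1)
  generate_genome(cfg_m, d2)
  scan1 <- run_scan(file.path(d1, "genome.fa"), file.path(d1, "annotation.gff3"),
                    file.path(d1, "domains.tsv"))
  scan2 <- run_scan(file.path(d2, "genome.fa"), file.path(d2, "annotation.gff3"),
                    file.path(d2, "domains.tsv"))
  expect_equal(scan1$summary, scan2$summary)
  cols <- c("gene_id", "exon_index", "coding_length", "res_start", "res_end",
            "domain_label", "type_label")
  expect_equal(scan1$microexons[, cols], scan2$microexons[, cols])
})
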