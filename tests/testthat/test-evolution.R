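test_that("global alignment: identical sequences align gapless with diagonal score", {
  B <- blosum62()
  al <- align_proteins("MKVLW", "MKVLW")
  expect_identical(al$a, "MKVLW")
  expect_identical(al$b, "MKVLW")
  expect_equal(al$score, sum(B[cbind(c("M","K","V","L","W"),
                                     c("M","K","V","L","W"))]))
  expect_error(align_proteins("MKB2", "MK"), "invalid residue")
  expect_error(align_proteins("", "MK"), "empty")
})

test_that("single-gap alignment matches brute-force enumeration of all alignments", {
  # all alignments of MKV vs MV with one gap: enumerate scores directly
  B <- blosum62()
  g1 <- 11  # gap_open 10 + 1 * gap_extend 1
  cands <- c(
    `MKV/-MV` = -g1 + B["K","M"] + B["V","V"],
    `MKV/M-V` = B["M","M"] - g1 + B["V","V"],
    `MKV/MV-` = B["M","M"] + B["K","V"] - g1)
  best <- max(cands)
  al <- align_proteins("MKV", "MV")
  expect_equal(al$score, best)
  expect_identical(al$a, "MKV")
  expect_identical(al$b, "M-V")
  # cross-check optimal score against Biostrings
  pa <- Biostrings::pairwiseAlignment("MKV", "MV",
                                      substitutionMatrix = blosum62(),
                                      gapOpening = 10, gapExtension = 1)
  expect_equal(al$score, Biostrings::score(pa))
})

test_that("alignment scores agree with Biostrings on random sequences", {
  set.seed(21)
  aas <- rownames(blosum62())[1:20]
  for (i in 1:10) {
    a <- paste0(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    b <- paste0(sample(aas, sample(10:40, 1), replace = TRUE), collapse = "")
    al <- align_proteins(a, b)
    pa <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = blosum62(),
                                        gapOpening = 10, gapExtension = 1)
    expect_equal(al$score, Biostrings::score(pa))
    # ungapping the rows returns the inputs
    expect_identical(gsub("-", "", al$a), a)
    expect_identical(gsub("-", "", al$b), b)
  }
})

test_that("codon threading replaces residues by codons and gaps by ---", {
  al <- list(a = "MK", b = "MK", score = 0)
  ca <- thread_codons(al, "ATGAAA", "ATGAAG")
  expect_identical(ca$codons_a, c("ATG", "AAA"))
  expect_identical(ca$codons_b, c("ATG", "AAG"))

  al2 <- list(a = "MKV", b = "M-V", score = 0)
  ca2 <- thread_codons(al2, "ATGAAAGTT", "ATGGTC")
  expect_identical(ca2$codons_b, c("ATG", "---", "GTC"))

  expect_error(thread_codons(al, "ATGAAATTT", "ATGAAG"), "length")
  expect_error(thread_codons(al, "ATGCCC", "ATGAAG"), "mismatch at residue 2")
})

test_that("NG86 worked micro-values match the brute-force oracle", {
  expect_equal(unname(ng86_sites("TTT")), c(1/3, 8/3))
  expect_equal(unname(ng86_sites("ATG")), c(0, 3))
  expect_equal(unname(ng86_differences("TTT", "TTC")), c(1, 0))
  expect_equal(unname(ng86_differences("TTT", "GTC")), c(1, 1))
  expect_equal(unname(ng86_differences("AAA", "AAA")), c(0, 0))
  expect_error(ng86_sites("TAA"), "stop")
  expect_error(ng86_differences("TAA", "TTT"), "stop")
  # spot agreement with the independent oracle on random codon pairs
  set.seed(5)
  for (i in 1:25) {
    a <- sample(SENSE, 1); b <- sample(SENSE, 1)
    expect_equal(unname(ng86_sites(a)), oracle_sites(a))
    expect_equal(unname(ng86_differences(a, b)), oracle_diffs(a, b))
  }
})

test_that("kaks sums sites and differences over comparable columns", {
  # identical 100-codon alignment: Ka = Ks = 0, ratio missing
  set.seed(9)
  cods <- sample(SENSE, 100, replace = TRUE)
  ca <- structure(list(codons_a = cods, codons_b = cods),
                  class = "codon_alignment")
  r <- kaks(ca)
  expect_equal(r$Ka, 0)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))
  expect_equal(r$S + r$N, 3 * r$n_codons)
  # full-alignment region is identical to the no-region call
  r2 <- kaks(ca, region = c(0, 100))
  expect_equal(r, r2)
  # symmetric in the two sequences
  cods_b <- sample(SENSE, 100, replace = TRUE)
  cab <- structure(list(codons_a = cods, codons_b = cods_b),
                   class = "codon_alignment")
  cba <- structure(list(codons_a = cods_b, codons_b = cods),
                   class = "codon_alignment")
  expect_equal(kaks(cab)[c("S","N","Sd","Nd","Ka","Ks")],
               kaks(cba)[c("S","N","Sd","Nd","Ka","Ks")])
  # gap and ambiguous columns are skipped (complete-codon deletion)
  cods2 <- cods; cods2[1] <- "---"; cods2[2] <- "ANT"
  cg <- structure(list(codons_a = cods2, codons_b = cods),
                  class = "codon_alignment")
  expect_equal(kaks(cg)$n_codons, 98)
  expect_error(kaks(structure(list(codons_a = "---", codons_b = "ATG"),
                              class = "codon_alignment")),
               "no comparable")
})

test_that("restricting kaks to disjoint windows sums counts exactly", {
  set.seed(17)
  cods_a <- sample(SENSE, 60, replace = TRUE)
  cods_b <- sample(SENSE, 60, replace = TRUE)
  ca <- structure(list(codons_a = cods_a, codons_b = cods_b),
                  class = "codon_alignment")
  w1 <- c(0, 20); w2 <- c(40, 60)
  ru <- kaks(ca, region = list(w1, w2))
  r1 <- kaks(ca, region = w1); r2 <- kaks(ca, region = w2)
  expect_equal(ru$Sd, r1$Sd + r2$Sd)
  expect_equal(ru$Nd, r1$Nd + r2$Nd)
  expect_equal(ru$S, r1$S + r2$S)
  expect_equal(ru$N, r1$N + r2$N)
})

test_that("signed-rank exact p matches enumeration and the base-R reference", {
  # n = 3, all differences positive
  expect_equal(compare_kaks_paired(c(2, 3, 4), c(1, 1, 1))$p_value, 0.125)
  # identical vectors -> error after dropping zeros
  expect_error(compare_kaks_paired(1:4, 1:4), "no usable pairs")
  # exact vs full 2^n enumeration for random data, n <= 10 (with ties)
  set.seed(31)
  for (i in 1:20) {
    n <- sample(4:10, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)
    d <- x - y
    if (all(d == 0)) next
    t1 <- compare_kaks_paired(x, y, alternative = "greater")
    expect_equal(t1$p_value, oracle_signed_rank_p(d, "greater"))
    t2 <- compare_kaks_paired(x, y, alternative = "less")
    expect_equal(t2$p_value, oracle_signed_rank_p(d, "less"))
  }
  # tie-free case agrees with stats::wilcox.test exact p
  set.seed(32)
  x <- rnorm(12); y <- rnorm(12)
  ref <- stats::wilcox.test(x, y, paired = TRUE, alternative = "greater",
                            exact = TRUE)
  expect_equal(compare_kaks_paired(x, y)$p_value, ref$p.value)
})

test_that("signed-rank normal approximation tracks the exact value at n = 25", {
  set.seed(41)
  x <- rnorm(25); y <- rnorm(25)
  exact <- compare_kaks_paired(x, y)$p_value
  # recompute via the approximation branch by inflating n past the cutoff
  d <- x - y
  r <- rank(abs(d)); W <- sum(r[d > 0]); n <- 25
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24
  approx <- pnorm((W - mu - 0.5) / sqrt(sigma2), lower.tail = FALSE)
  expect_lt(abs(exact - approx), 0.01)
  # approximation branch engages above the cutoff and stays sane
  t30 <- compare_kaks_paired(rnorm(30) + 0.5, rnorm(30))
  expect_identical(t30$method, "normal approximation")
  expect_true(t30$p_value >= 0 && t30$p_value <= 1)
})

test_that("Poisson distance follows the closed form and caps saturation", {
  expect_equal(as.numeric(poisson_distance("MKVL", "MKVL")), 0)
  # p = 0.1 -> -ln(0.9)
  a <- strrep("A", 10); b <- paste0(strrep("A", 9), "C")
  expect_equal(as.numeric(poisson_distance(a, b)), -log(0.9))
  d <- poisson_distance("AAAA", "CCCC")
  expect_equal(as.numeric(d), 10)
  expect_true(attr(d, "saturated"))
  # gapped columns excluded
  expect_equal(as.numeric(poisson_distance("MK-L", "MKV-")), 0)
  expect_error(poisson_distance("--", "AA"), "no comparable")
})

test_that("neighbor joining solves the three-point closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ exactly recovers additive matrices from planted random trees", {
  set.seed(19)
  for (rep in 1:15) {
    n_taxa <- sample(4:8, 1)
    tr0 <- ape::rtree(n_taxa, br = function(n) runif(n, 0.1, 1))
    tr0 <- ape::unroot(tr0)
    D <- ape::cophenetic.phylo(tr0)
    D <- D[sort(rownames(D)), sort(colnames(D))]
    tr <- neighbor_joining(D)
    # path lengths reproduced within 1e-9
    D2 <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
    expect_lt(max(abs(D2 - D)), 1e-9)
    # topology identical to the planted tree
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), tr0)), 0)
    # taxon-order permutation gives the same unrooted topology
    p <- sample(n_taxa)
    trp <- neighbor_joining(D[p, p])
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(trp), ape::unroot(tr))), 0)
  }
})

test_that("NJ agrees with ape::nj on random non-additive matrices", {
  set.seed(23)
  for (rep in 1:5) {
    n <- 6
    M <- matrix(runif(n * n, 0.2, 2), n, n)
    D <- (M + t(M)) / 2; diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
  }
})

test_that("bootstrap supports are seeded, reproducible and high for clear splits", {
  # two well-separated clades: AB vs CD with a long internal branch
  rows <- c(A = strrep("A", 30), B = paste0(strrep("A", 28), "CC"),
            C = strrep("W", 30), D = paste0(strrep("W", 28), "YY"))
  t1 <- bootstrap_support(rows, n_reps = 200, seed = 99)
  expect_true(all(as.numeric(t1$node.label) >= 95, na.rm = TRUE))
  t2 <- bootstrap_support(rows, n_reps = 200, seed = 99)
  expect_identical(t1$node.label, t2$node.label)
  t3 <- bootstrap_support(rows, n_reps = 0, seed = 1)
  expect_null(t3$node.label)
})

test_that("align_to_reference produces equal-length rows anchored on the longest member", {
  seqs <- c(s1 = "MKVLWAALLV", s2 = "MKVLWAALL", s3 = "MKVWAALLV")
  rows <- align_to_reference(seqs)
  expect_identical(attr(rows, "reference"), "s1")
  expect_true(all(nchar(rows) == nchar(seqs[["s1"]])))
  expect_identical(unname(rows["s1"]), seqs[["s1"]])
})
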