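# Independent brute-force oracles and small fixture builders. These stay
# deliberately separate from the package's own code paths: the NG86 oracle
# enumerates mutants and pathways by recursion over a plain codon table, and
# the signed-rank oracle enumerates all 2^n sign assignments.

CODE <- Biostrings::GENETIC_CODE
SENSE <- names(CODE)[CODE != "*"]

# --- NG86 oracle ------------------------------------------------------------

oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; usable <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      m <- codon
      substr(m, pos, pos) <- b
      if (CODE[[m]] == "*") next
      usable <- usable + 1
      if (CODE[[m]] == CODE[[codon]]) syn <- syn + 1
    }
    if (usable > 0) s <- s + syn / usable
  }
  c(s, 3 - s)
}

# recursive pathway enumeration (depth-first over remaining positions)
oracle_diffs <- function(a, b) {
  paths <- list()
  recurse <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      paths[[length(paths) + 1L]] <<- c(sd = sd, nd = nd,
                                        blocked = as.numeric(blocked))
      return()
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(b, pos, pos)
      step_blocked <- blocked || CODE[[nxt]] == "*"
      syn <- !step_blocked && CODE[[nxt]] == CODE[[cur]]
      recurse(nxt, setdiff(remaining, pos),
              sd + as.numeric(syn), nd + as.numeric(!syn), step_blocked)
    }
  }
  dpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (!length(dpos)) return(c(0, 0))
  recurse(a, dpos, 0, 0, FALSE)
  m <- do.call(rbind, paths)
  ok <- m[, "blocked"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(mean(m[, "sd"]), mean(m[, "nd"]))
}

# --- signed-rank oracle -----------------------------------------------------

oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wperm <- as.vector(signs %*% r)
  if (alternative == "greater") mean(Wperm >= W) else mean(Wperm <= W)
}

# --- tiny transcript fixtures ----------------------------------------------

# Build a transcript model directly (no files): exon/CDS structure given as
# 0-based half-open genomic intervals on a named chromosome.
make_transcript <- function(id = "t1", gene_id = "g1", chrom = "chr1",
                            strand = "+", exons, cds, phase0 = 0L) {
  phases <- rep(NA_integer_, nrow(cds))
  phases[1] <- phase0
  list(id = id, gene_id = gene_id, chrom = chrom, strand = strand,
       exons = exons, cds = cbind(cds, phase = phases),
       cds_seq = "", protein = "", valid = TRUE)
}

iv <- function(start, end) data.frame(start = as.integer(start),
                                      end = as.integer(end))

# Random multi-exon transcript on either strand with whole-codon CDS total;
# returns the model plus a genome in which its CDS is a recorded codon string.
random_transcript <- function(seed_offset = 0L) {
  k <- sample(1:5, 1)
  lens <- sample(3:120, k, replace = TRUE)
  pad <- (3 - sum(lens) %% 3) %% 3
  lens[k] <- lens[k] + pad
  introns <- if (k > 1) sample(10:200, k - 1, replace = TRUE) else integer(0)
  starts <- 10L + c(0L, cumsum(lens[-k] + introns))
  ends <- starts + lens
  strand <- sample(c("+", "-"), 1)
  chrom_len <- max(ends) + 10L
  seq <- paste0(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                collapse = "")
  tx <- make_transcript(strand = strand,
                        exons = iv(starts, ends), cds = iv(starts, ends))
  if (strand == "-") {  # transcript order: descending genomic start
    tx$exons <- tx$exons[order(-tx$exons$start), ]
    tx$cds <- tx$cds[order(-tx$cds$start), ]
    tx$cds$phase <- c(0L, rep(NA_integer_, k - 1))
  }
  list(tx = tx, genome = c(chr1 = seq), cds_len = sum(lens))
}

# --- file fixture: a small hand-written GFF3 + genome ------------------------

write_toy_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t11\t130\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t11\t130\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\ttoy\texon\t11\t40\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\texon\t61\t130\t.\t+\t.\tParent=g1.t1",
    "chr1\ttoy\tCDS\t21\t40\t.\t+\t0\tParent=g1.t1",
    "chr1\ttoy\tCDS\t61\t109\t.\t+\t1\tParent=g1.t1",
    "chr1\ttoy\tmRNA\t11\t130\t.\t+\t.\tID=g1.t2;Parent=g1",
    "chr1\ttoy\texon\t11\t130\t.\t+\t.\tParent=g1.t2",
    "chr1\ttoy\tCDS\t21\t110\t.\t+\t0\tParent=g1.t2",
    "chr2\ttoy\tgene\t100\t151\t.\t-\t.\tID=g2",
    "chr2\ttoy\tmRNA\t100\t151\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr2\ttoy\texon\t100\t151\t.\t-\t.\tParent=g2.t1",
    "chr2\ttoy\tCDS\t100\t151\t.\t-\t.\tParent=g2.t1"), path)
  path
}
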