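# Synthetic genome / annotation / domain-table generator with planted ground
# truth: multi-exon genes on both strands, micro-exon architectures of the
# recurrent AP2-domain classes (9/26/31/45 nt) and the tandem K-box pair,
# domain intervals consistent with the architectures, and ortholog CDS pairs
# diverged under a specified nonsynonymous acceptance probability omega.
#
# In-domain micro-exon proportions are planted deterministically (exact
# counts), never sampled, so downstream enrichment summaries are exact.

#' Configuration for the synthetic-genome generator
#'
#' Defaults emulate a rice-like transcription-factor cohort: 113 ERF/DREB,
#' 24 AP2-subfamily, 4 RAV and 2 other AP2/ERF genes, 24 MIKC genes and 5
#' domain-less genes. Each AP2-subfamily gene carries the four recurrent
#' in-domain micro-exons (R1M1 9 nt, the tandem R1M2 26 nt + R1M3 31 nt,
#' R2M1 45 nt); each MIKC gene carries the tandem K-box pair (M1 42 nt,
#' M2 45 nt) ending at the domain C terminus. Additional 9-nt micro-exons
#' are planted in inter-domain linkers to hit the requested in-domain
#' proportions exactly (0.768 for AP2, 0.923 for K-box by default); the gene
#' counts are chosen so these proportions are exactly representable.
#'
#' @param seed mandatory integer seed
#' @param n_genes named integer vector: erf_dreb, ap2, rav, other, mikc, none
#' @param ap2_in_domain_fraction,mikc_in_domain_fraction target proportions
#'   of family micro-exons inside the hallmark domain
#' @param strand "random", "plus" or "minus"
#' @param strand_prob probability of "+" when strand = "random"
#' @param intron_range,utr_range uniform length ranges (nt)
#' @param within_family_divergence target synonymous divergence (Ks) of each
#'   gene from its family ancestor (0 = identical sequences)
#' @param within_family_omega nonsynonymous acceptance probability used when
#'   diverging family members
#' @param extra_isoforms also emit a shorter second isoform for the first
#'   AP2-subfamily gene (exercises representative-isoform selection)
#' @param tpm_conditions number of conditions for [generate_tpm()]
#' @return list of class `synthetic_config`
#' @export
synthetic_config <- function(seed,
                             n_genes = c(erf_dreb = 113L, ap2 = 24L,
                                         rav = 4L, other = 2L,
                                         mikc = 24L, none = 5L),
                             ap2_in_domain_fraction = 0.768,
                             mikc_in_domain_fraction = 0.923,
                             strand = c("random", "plus", "minus"),
                             strand_prob = 0.5,
                             intron_range = c(60L, 500L),
                             utr_range = c(50L, 200L),
                             within_family_divergence = 0.15,
                             within_family_omega = 0.2,
                             extra_isoforms = TRUE,
                             tpm_conditions = 6L) {
  if (missing(seed)) stop("seed is mandatory")
  need <- c("erf_dreb", "ap2", "rav", "other", "mikc", "none")
  if (!all(names(n_genes) %in% need))
    stop("unknown gene class in n_genes: ",
         paste(setdiff(names(n_genes), need), collapse = ", "))
  full <- setNames(rep(0L, length(need)), need)
  full[names(n_genes)] <- as.integer(n_genes)
  if (any(full < 0L)) stop("gene counts must be >= 0")
  stopifnot(ap2_in_domain_fraction > 0, ap2_in_domain_fraction <= 1,
            mikc_in_domain_fraction > 0, mikc_in_domain_fraction <= 1)
  structure(list(seed = as.integer(seed), n_genes = full,
                 ap2_in_domain_fraction = ap2_in_domain_fraction,
                 mikc_in_domain_fraction = mikc_in_domain_fraction,
                 strand = match.arg(strand), strand_prob = strand_prob,
                 intron_range = as.integer(intron_range),
                 utr_range = as.integer(utr_range),
                 within_family_divergence = within_family_divergence,
                 within_family_omega = within_family_omega,
                 extra_isoforms = isTRUE(extra_isoforms),
                 tpm_conditions = as.integer(tpm_conditions)),
            class = "synthetic_config")
}

# ---- gene blueprints -------------------------------------------------------
# Residue coordinates are 0-based half-open; exon lengths are CDS nt
# (the trailing stop codon lives in the last exon). Non-micro exons are all
# > 51 nt so only the planted micro-exons are callable.

blueprint <- function(subfamily, n_out = 0L) {
  dom <- function(label, accession, start, end)
    data.frame(label = label, accession = accession, start = start, end = end,
               stringsAsFactors = FALSE)
  mex <- function(exon_index, length, context, type, in_domain)
    data.frame(exon_index = exon_index, length = length, context = context,
               type = type, in_domain = in_domain, stringsAsFactors = FALSE)
  switch(subfamily,
    ap2 = {
      exons <- switch(as.character(n_out),
        "0" = c(114L, 9L, 57L, 26L, 31L, 263L, 45L, 238L),
        "1" = c(114L, 9L, 57L, 26L, 31L, 73L, 9L, 181L, 45L, 238L),
        "2" = c(114L, 9L, 57L, 26L, 31L, 73L, 9L, 61L, 9L, 111L, 45L, 238L),
        stop("at most 2 linker micro-exons per AP2 gene"))
      micros <- rbind(
        mex(1L, 9L, "AP2/R1", "R1M1", TRUE),
        mex(3L, 26L, "AP2/R1", "R1M2", TRUE),
        mex(4L, 31L, "AP2/R1", "R1M3", TRUE),
        if (n_out >= 1L) mex(6L, 9L, "none", "unclassified", FALSE),
        if (n_out >= 2L) mex(8L, 9L, "none", "unclassified", FALSE),
        mex(length(exons) - 2L, 45L, "AP2/R2", "R2M1", TRUE))
      list(protein_len = 260L,
           domains = rbind(dom("AP2", "PF00847", 30L, 98L),
                           dom("AP2", "PF00847", 150L, 218L)),
           exon_lens = exons, micros = micros)
    },
    erf_dreb = list(protein_len = 200L,
                    domains = dom("AP2", "PF00847", 40L, 100L),
                    exon_lens = c(201L, 201L, 201L),
                    micros = mex(integer(0), integer(0), character(0),
                                 character(0), logical(0))),
    rav = list(protein_len = 250L,
               domains = rbind(dom("AP2", "PF00876", 10L, 70L),
                               dom("B3", "PF02362", 100L, 190L)),
               exon_lens = 753L,
               micros = mex(integer(0), integer(0), character(0),
                            character(0), logical(0))),
    other = list(protein_len = 180L,
                 domains = rbind(dom("AP2", "PF00847", 10L, 70L),
                                 dom("other", "PF99999", 90L, 150L)),
                 exon_lens = c(300L, 243L),
                 micros = mex(integer(0), integer(0), character(0),
                              character(0), logical(0))),
    mikc = {
      exons <- if (n_out == 0L) c(204L, 204L, 42L, 45L, 168L)
               else c(200L, 9L, 199L, 42L, 45L, 168L)
      base <- if (n_out == 0L) 2L else 3L
      micros <- rbind(
        if (n_out >= 1L) mex(1L, 9L, "none", "unclassified", FALSE),
        mex(base, 42L, "K-box", "M1", TRUE),
        mex(base + 1L, 45L, "K-box", "M2", TRUE))
      list(protein_len = 220L,
           domains = rbind(dom("SRF-TF", "PF00319", 2L, 59L),
                           dom("K-box", "PF01486", 75L, 165L)),
           exon_lens = exons, micros = micros)
    },
    none = list(protein_len = 150L,
                domains = dom(character(0), character(0), integer(0),
                              integer(0)),
                exon_lens = c(230L, 223L),
                micros = mex(integer(0), integer(0), character(0),
                             character(0), logical(0))),
    stop("unknown subfamily blueprint: ", subfamily))
}

# split `total` extra micro-exons over `n` genes, at most `cap` per gene
distribute_out <- function(total, n, cap) {
  if (total > n * cap)
    stop("infeasible: ", total, " linker micro-exons over ", n,
         " genes (max ", cap, " each)")
  k2 <- if (cap >= 2L) max(0L, total - n) else 0L
  k1 <- total - 2L * k2
  c(rep(2L, k2), rep(1L, k1), rep(0L, n - k2 - k1))
}

random_sense_cds <- function(n_aa) {
  sc <- setdiff(sense_codons(), c("ATG"))
  paste0(c("ATG", sample(sc, n_aa - 1L, replace = TRUE), "TAA"),
         collapse = "")
}

random_bases <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# ---- sequence divergence ---------------------------------------------------

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

realized_ks <- function(codons_a, codons_b) {
  caln <- structure(list(codons_a = codons_a, codons_b = codons_b),
                    class = "codon_alignment")
  res <- tryCatch(kaks(caln), error = function(e) NULL)
  if (is.null(res) || is.na(res$Ks)) Inf else res$Ks
}

# Propose random single-nucleotide substitutions on the chosen lineages:
# synonymous proposals are always accepted, nonsynonymous ones with
# probability omega, stop-creating ones never. Stops when the oracle-counted
# synonymous divergence between the two lineages reaches target_ks. Uses the
# current RNG state.
evolve_codons <- function(codons_a, codons_b, omega, target_ks,
                          lineages = c(1L, 2L), max_proposals = NULL) {
  gc <- genetic_code()
  L <- length(codons_a)
  if (is.null(max_proposals)) max_proposals <- 4000L * L
  if (target_ks <= 0) return(list(a = codons_a, b = codons_b))
  bases <- c("A", "C", "G", "T")
  prop <- 0L
  check_every <- max(1L, L %/% 100L)
  accepted_since_check <- 0L
  repeat {
    for (side in lineages) {
      prop <- prop + 1L
      if (prop > max_proposals)
        stop("target synonymous divergence unreachable within proposal cap")
      cods <- if (side == 1L) codons_a else codons_b
      ci <- sample.int(L, 1L)
      pos <- sample.int(3L, 1L)
      old <- cods[ci]
      nb <- sample(setdiff(bases, substr(old, pos, pos)), 1L)
      new <- old
      substr(new, pos, pos) <- nb
      if (gc[[new]] == "*") next
      accept <- gc[[new]] == gc[[old]] || runif(1) < omega
      if (!accept) next
      cods[ci] <- new
      if (side == 1L) codons_a <- cods else codons_b <- cods
      accepted_since_check <- accepted_since_check + 1L
      if (accepted_since_check >= check_every) {
        accepted_since_check <- 0L
        if (realized_ks(codons_a, codons_b) >= target_ks)
          return(list(a = codons_a, b = codons_b))
      }
    }
  }
}

#' Evolve an ortholog CDS pair from a common ancestor
#'
#' Both lineages accumulate random single-nucleotide substitutions
#' (synonymous accepted with probability 1, nonsynonymous with probability
#' `omega`, stop-creating rejected) until the realized synonymous divergence
#' between them -- measured by NG86 counting on the true pair, independently
#' of any estimator under test -- reaches `target_ks`.
#'
#' @param ancestor_cds in-frame CDS without internal stops (a trailing stop
#'   codon, if present, is held fixed)
#' @param omega nonsynonymous acceptance probability (>= 0)
#' @param target_ks target pairwise synonymous divergence (Jukes-Cantor
#'   corrected)
#' @param seed integer seed
#' @return list with `cds_1` and `cds_2`
#' @export
evolve_pair <- function(ancestor_cds, omega, target_ks, seed) {
  if (nchar(ancestor_cds) %% 3L != 0L) stop("ancestor length not a multiple of 3")
  if (omega < 0) stop("omega must be >= 0")
  set.seed(seed)
  cods <- split_codons(toupper(ancestor_cds))
  gc <- genetic_code()
  has_stop <- gc[cods] == "*"
  if (any(has_stop[-length(cods)])) stop("ancestor has an internal stop codon")
  trailing_stop <- has_stop[length(cods)]
  core <- if (trailing_stop) cods[-length(cods)] else cods
  res <- evolve_codons(core, core, omega, target_ks)
  tail <- if (trailing_stop) cods[length(cods)] else character(0)
  list(cds_1 = paste0(c(res$a, tail), collapse = ""),
       cds_2 = paste0(c(res$b, tail), collapse = ""))
}

# Diverge one CDS away from a fixed ancestor (used for within-family
# sequence variation); uses current RNG state.
diverge_from <- function(cds, omega, target_ks) {
  if (target_ks <= 0) return(cds)
  cods <- split_codons(cds)
  gc <- genetic_code()
  n <- length(cods)
  trailing_stop <- gc[[cods[n]]] == "*"
  core <- if (trailing_stop) cods[-n] else cods
  res <- evolve_codons(core, core, omega, target_ks, lineages = 1L)
  paste0(c(res$a, if (trailing_stop) cods[n]), collapse = "")
}

# ---- genome emission -------------------------------------------------------

# Build one gene's genomic record from a blueprint and a CDS string laid out
# on a "+" virtual strand, then flipped if strand is "-".
build_gene <- function(gene_id, bp, cds_with_stop, strand, intron_range,
                       utr_range, extra_isoform = FALSE) {
  exl <- bp$exon_lens
  ne <- length(exl)
  u5 <- sample(utr_range[1]:utr_range[2], 1L)
  u3 <- sample(utr_range[1]:utr_range[2], 1L)
  introns <- if (ne > 1L) sample(intron_range[1]:intron_range[2], ne - 1L,
                                 replace = TRUE) else integer(0)
  flank <- 100L
  ex_glens <- exl + ifelse(seq_len(ne) == 1L, u5, 0L) +
    ifelse(seq_len(ne) == ne, u3, 0L)
  ex_start <- flank + c(0L, cumsum(ex_glens[-ne] + introns))
  ex_end <- ex_start + ex_glens
  cds_start <- ex_start + ifelse(seq_len(ne) == 1L, u5, 0L)
  cds_end <- ex_end - ifelse(seq_len(ne) == ne, u3, 0L)
  cum_before <- c(0L, cumsum(exl))[seq_len(ne)]
  phase <- (3L - cum_before %% 3L) %% 3L
  chrom_len <- ex_end[ne] + flank
  seqv <- strsplit(random_bases(chrom_len), "")[[1]]
  cdsv <- strsplit(cds_with_stop, "")[[1]]
  off <- 0L
  for (i in seq_len(ne)) {
    seqv[(cds_start[i] + 1L):cds_end[i]] <- cdsv[(off + 1L):(off + exl[i])]
    off <- off + exl[i]
  }
  chrom_seq <- paste0(seqv, collapse = "")
  chrom <- paste0("chr_", gene_id)
  if (strand == "-") {
    chrom_seq <- revcomp(chrom_seq)
    flip <- function(s, e) list(start = chrom_len - e, end = chrom_len - s)
    fe <- flip(ex_start, ex_end); ex_start <- fe$start; ex_end <- fe$end
    fc <- flip(cds_start, cds_end); cds_start <- fc$start; cds_end <- fc$end
  }
  tx_id <- paste0(gene_id, ".t1")
  gff <- function(type, s0, e0, ph, attrs) {
    sprintf("%s\tmexscan_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, s0 + 1L, e0, strand, ph, attrs)
  }
  lines <- c(
    gff("gene", min(ex_start), max(ex_end), ".", paste0("ID=", gene_id)),
    gff("mRNA", min(ex_start), max(ex_end), ".",
        paste0("ID=", tx_id, ";Parent=", gene_id)))
  for (i in seq_len(ne)) {
    lines <- c(lines,
      gff("exon", ex_start[i], ex_end[i], ".", paste0("Parent=", tx_id)),
      gff("CDS", cds_start[i], cds_end[i], phase[i], paste0("Parent=", tx_id)))
  }
  if (extra_isoform) {
    # shorter isoform: CDS truncated at the first codon-aligned exon boundary
    # past half the CDS (exons unchanged)
    cums <- cumsum(exl)
    k <- which(cums %% 3L == 0L & cums < sum(exl) & cums >= sum(exl) %/% 4L)[1]
    if (!is.na(k)) {
      tx2 <- paste0(gene_id, ".t2")
      lines <- c(lines, gff("mRNA", min(ex_start), max(ex_end), ".",
                            paste0("ID=", tx2, ";Parent=", gene_id)))
      for (i in seq_len(ne)) {
        lines <- c(lines, gff("exon", ex_start[i], ex_end[i], ".",
                              paste0("Parent=", tx2)))
        if (i <= k)
          lines <- c(lines, gff("CDS", cds_start[i], cds_end[i], phase[i],
                                paste0("Parent=", tx2)))
      }
    }
  }
  list(chrom = chrom, seq = chrom_seq, gff = lines, tx_id = tx_id)
}

#' Generate a synthetic genome with planted micro-exon and domain truth
#'
#' Emits a genome FASTA, a GFF3 annotation, an InterProScan-style domain TSV
#' for the representative proteins and a JSON ground-truth file into
#' `outdir`. Same seed, same files. Genes within a family descend from a
#' common ancestral CDS (divergence set by the config), so family members
#' are genuinely homologous.
#'
#' @param config a [synthetic_config()]
#' @param outdir output directory (created if missing)
#' @return invisibly, a list with `paths` (genome, gff3, domains, truth) and
#'   `truth` (list with `families` and `microexons` data frames)
#' @export
generate_genome <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  set.seed(config$seed)
  ng <- config$n_genes

  n_out_ap2 <- 0L
  if (ng[["ap2"]] > 0L) {
    n_in <- 4L * ng[["ap2"]]
    n_out_ap2 <- as.integer(round(n_in / config$ap2_in_domain_fraction)) - n_in
  }
  n_out_mikc <- 0L
  if (ng[["mikc"]] > 0L) {
    n_in <- 2L * ng[["mikc"]]
    n_out_mikc <- as.integer(round(n_in / config$mikc_in_domain_fraction)) - n_in
  }
  ap2_out <- distribute_out(n_out_ap2, ng[["ap2"]], 2L)
  mikc_out <- distribute_out(n_out_mikc, ng[["mikc"]], 1L)

  plan <- list()
  add <- function(subfam, prefix, count, out_counts = NULL) {
    for (i in seq_len(count)) {
      plan[[length(plan) + 1L]] <<- list(
        gene_id = sprintf("%s%03d", prefix, i), subfam = subfam,
        n_out = if (is.null(out_counts)) 0L else out_counts[i])
    }
  }
  add("erf_dreb", "ERF", ng[["erf_dreb"]])
  add("ap2", "AP2G", ng[["ap2"]], ap2_out)
  add("rav", "RAV", ng[["rav"]])
  add("other", "OTH", ng[["other"]])
  add("mikc", "MIKC", ng[["mikc"]], mikc_out)
  add("none", "NONE", ng[["none"]])

  # one ancestral CDS per subfamily; members diverge from it
  anc <- list()
  for (sf in unique(vapply(plan, `[[`, "", "subfam"))) {
    anc[[sf]] <- random_sense_cds(blueprint(sf)$protein_len)
  }

  genome <- character(0)
  gff_lines <- c("##gff-version 3")
  dom_lines <- character(0)
  fam_rows <- list(); mex_rows <- list()
  family_of <- c(erf_dreb = "AP2/ERF", ap2 = "AP2/ERF", rav = "AP2/ERF",
                 other = "AP2/ERF", mikc = "MIKC", none = "none")
  subfam_of <- c(erf_dreb = "ERF/DREB", ap2 = "AP2", rav = "RAV",
                 other = "other", mikc = NA_character_, none = NA_character_)
  first_ap2_done <- FALSE

  for (g in plan) {
    bp <- blueprint(g$subfam, g$n_out)
    cds <- diverge_from(anc[[g$subfam]], config$within_family_omega,
                        config$within_family_divergence)
    strand <- switch(config$strand,
      plus = "+", minus = "-",
      random = if (runif(1) < config$strand_prob) "+" else "-")
    iso <- config$extra_isoforms && g$subfam == "ap2" && !first_ap2_done
    if (iso) first_ap2_done <- TRUE
    rec <- build_gene(g$gene_id, bp, cds, strand, config$intron_range,
                      config$utr_range, extra_isoform = iso)
    genome[rec$chrom] <- rec$seq
    gff_lines <- c(gff_lines, rec$gff)
    if (nrow(bp$domains)) {
      cc <- coord_to_1based(bp$domains$start, bp$domains$end)
      dom_lines <- c(dom_lines, sprintf(
        "%s\t-\t%d\tPfam\t%s\t-\t%d\t%d", rec$tx_id, bp$protein_len,
        bp$domains$accession, cc$start, cc$end))
    }
    fam_rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, family = family_of[[g$subfam]],
      subfamily = subfam_of[[g$subfam]], stringsAsFactors = FALSE)
    if (nrow(bp$micros)) {
      m <- bp$micros
      m$gene_id <- g$gene_id; m$transcript_id <- rec$tx_id
      mex_rows[[g$gene_id]] <- m[, c("gene_id", "transcript_id", "exon_index",
                                     "length", "context", "type", "in_domain")]
    }
  }

  truth <- list(
    families = do.call(rbind, c(fam_rows, list(make.row.names = FALSE))),
    microexons = if (length(mex_rows))
      do.call(rbind, c(mex_rows, list(make.row.names = FALSE)))
    else data.frame())

  paths <- list(genome = file.path(outdir, "genome.fa"),
                gff3 = file.path(outdir, "annotation.gff3"),
                domains = file.path(outdir, "domains.tsv"),
                truth = file.path(outdir, "ground_truth.json"))
  write_fasta(genome, paths$genome)
  writeLines(gff_lines, paths$gff3)
  writeLines(dom_lines, paths$domains)
  jsonlite::write_json(truth, paths$truth, dataframe = "rows")
  invisible(list(paths = paths, truth = truth))
}

#' Generate a synthetic TPM expression table
#'
#' Log-normal abundances with one planted tissue-specific gene (strongly
#' elevated in the first condition).
#'
#' @param gene_ids character vector of gene ids (rows)
#' @param n_conditions number of conditions (>= 2)
#' @param seed integer seed
#' @param tissue_specific id of the planted tissue-specific gene (default
#'   the first); `NULL` for none
#' @return numeric matrix, genes x conditions
#' @export
generate_tpm <- function(gene_ids, n_conditions = 6L, seed,
                         tissue_specific = gene_ids[1]) {
  stopifnot(n_conditions >= 2L)
  set.seed(seed)
  m <- matrix(exp(rnorm(length(gene_ids) * n_conditions, 3, 1)),
              nrow = length(gene_ids),
              dimnames = list(gene_ids,
                              paste0("condition_", seq_len(n_conditions))))
  if (!is.null(tissue_specific) && tissue_specific %in% gene_ids)
    m[tissue_specific, 1] <- m[tissue_specific, 1] * 50
  m
}
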