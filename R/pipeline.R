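# End-to-end orchestration: read -> assemble -> classify -> call -> assign ->
# type -> tandem -> summarize -> (optional) Ka/Ks + signed-rank comparison ->
# (optional) NJ tree of domain sequences.

#' Z-score transform of a TPM expression matrix
#'
#' Per gene row: `x -> log2(x + 1)`, then centred and scaled across
#' conditions. Zero-variance rows (e.g. an all-zero gene) become all-zero
#' rather than NaN.
#'
#' @param tpm non-negative numeric matrix, genes x conditions
#' @return z-score matrix of the same shape
#' @export
zscore_expression <- function(tpm) {
  if (any(tpm < 0)) stop("TPM values must be non-negative")
  lg <- log2(tpm + 1)
  t(apply(lg, 1, function(x) {
    s <- sd(x)
    if (is.na(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}

# alignment-column interval (0-based half-open) covering residues [rs, re)
# of the first sequence of a pairwise alignment
residues_to_columns <- function(aligned_a, rs, re) {
  cols <- which(strsplit(aligned_a, "")[[1]] != "-")
  if (re > length(cols)) return(NULL)
  c(cols[rs + 1L] - 1L, cols[re])
}

hallmark_domain <- function(hits_protein, family) {
  lab <- if (family == "MIKC") "K-box" else "AP2"
  h <- hits_protein[hits_protein$label == lab, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h[order(h$start), , drop = FALSE][1, ]
}

# Ka/Ks of the hallmark domain and of every micro-exon window of gene_a,
# for one ortholog/paralog gene pair.
pair_kaks_rows <- function(pair_a, pair_b, genes, hits, micros, families) {
  ga <- genes[[pair_a]]; gb <- genes[[pair_b]]
  if (is.null(ga) || is.null(gb)) stop("unknown gene id in pair list")
  ta <- ga$transcripts[[ga$representative]]
  tb <- gb$transcripts[[gb$representative]]
  aln <- align_proteins(ta$protein, tb$protein)
  trailing <- function(tx) substr(tx$cds_seq, 1, 3L * nchar(tx$protein))
  caln <- thread_codons(aln, trailing(ta), trailing(tb))
  fam <- families$family[families$gene_id == pair_a]
  dom <- hallmark_domain(hits[hits$protein_id == ta$id, , drop = FALSE],
                         fam)
  if (is.null(dom)) return(NULL)
  dom_cols <- residues_to_columns(aln$a, dom$start, dom$end)
  if (is.null(dom_cols)) return(NULL)
  row1 <- function(region_label, res) {
    data.frame(gene_a = pair_a, gene_b = pair_b, region = region_label,
               S = res$S, N = res$N, Sd = res$Sd, Nd = res$Nd,
               Ka = res$Ka, Ks = res$Ks, ratio = res$ratio,
               n_codons = res$n_codons, stringsAsFactors = FALSE)
  }
  out <- row1("domain", kaks(caln, dom_cols))
  mex <- micros[micros$gene_id == pair_a, , drop = FALSE]
  for (i in seq_len(nrow(mex))) {
    cols <- residues_to_columns(aln$a, mex$res_start[i], mex$res_end[i])
    if (is.null(cols)) next
    lab <- if (!is.na(mex$type_label[i]) && mex$type_label[i] != "unclassified")
      mex$type_label[i] else paste0("exon", mex$exon_index[i])
    res <- tryCatch(kaks(caln, cols), error = function(e) NULL)
    if (!is.null(res)) out <- rbind(out, row1(lab, res))
  }
  out
}

#' Run the full micro-exon / domain scan
#'
#' Executes the whole pipeline on a genome + GFF3 + domain-hit table:
#' transcript assembly, representative-isoform selection, family
#' classification, micro-exon calling, domain assignment, typing, tandem
#' detection and overlap summaries; optionally Ka/Ks of micro-exon windows
#' vs whole domains over a supplied gene-pair list (with a one-sided
#' signed-rank comparison), a neighbor-joining tree of domain sequences, and
#' a z-scored expression matrix. When `out_dir` is given, all report tables,
#' the newick tree and a JSON run manifest are written there.
#'
#' @param genome path to the genome FASTA
#' @param gff3 path to the GFF3 annotation
#' @param domains path to the domain-hit TSV (InterProScan layout)
#' @param tpm optional path to a TPM table (TSV, genes x conditions, first
#'   column gene ids)
#' @param pairs optional data frame (or TSV path) with columns gene_a,
#'   gene_b for the Ka/Ks stage
#' @param out_dir optional output directory
#' @param threshold_nt micro-exon coding-length threshold (default 51)
#' @param accession_map accession -> label map, see [default_accession_map()]
#' @param type_config micro-exon type table, see [default_type_config()]
#' @param min_overlap_aa minimum residue overlap for domain assignment
#' @param tree_domain optional domain label ("AP2" or "K-box") to build an
#'   NJ tree of domain sequences
#' @param bootstrap_reps bootstrap replicates for the tree (default 0)
#' @param alternative direction of the signed-rank comparison
#'   (micro-exon window vs domain; default "greater")
#' @param seed integer seed used by the bootstrap
#' @return list of class `mexscan_result` with elements `families`,
#'   `microexons`, `summary`, `kaks`, `wilcoxon`, `tree`, `zscores`,
#'   `manifest`
#' @export
run_scan <- function(genome, gff3, domains, tpm = NULL, pairs = NULL,
                     out_dir = NULL, threshold_nt = 51L,
                     accession_map = default_accession_map(),
                     type_config = default_type_config(),
                     min_overlap_aa = 1L, tree_domain = NULL,
                     bootstrap_reps = 0L,
                     alternative = c("greater", "less"), seed = 1L) {
  alternative <- match.arg(alternative)
  genome_seqs <- read_fasta(genome)
  ann <- read_gff3(gff3)
  hits <- read_domain_table(domains, accession_map)
  genes <- assemble_transcripts(ann, genome_seqs)

  families <- classify_families(genes, hits)
  micros <- do.call(rbind, c(lapply(genes, call_microexons,
                                    threshold_nt = threshold_nt),
                             list(make.row.names = FALSE)))
  micros <- assign_domain(micros, hits, min_overlap_aa = min_overlap_aa)
  micros <- classify_type(micros, type_config)
  micros <- detect_tandem(micros)
  summary <- summarize_overlap(micros, families)

  kaks_tab <- NULL; wilcox <- NULL
  if (!is.null(pairs)) {
    if (is.character(pairs))
      pairs <- read.table(pairs, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
    rows <- lapply(seq_len(nrow(pairs)), function(i) {
      pair_kaks_rows(pairs$gene_a[i], pairs$gene_b[i], genes, hits,
                     micros, families)
    })
    kaks_tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (!is.null(kaks_tab) && nrow(kaks_tab)) {
      dom_idx <- kaks_tab$region == "domain"
      dom_ratio <- setNames(kaks_tab$ratio[dom_idx],
                            paste(kaks_tab$gene_a, kaks_tab$gene_b)[dom_idx])
      win <- kaks_tab[kaks_tab$region != "domain", , drop = FALSE]
      key <- paste(win$gene_a, win$gene_b)
      wilcox <- tryCatch(
        compare_kaks_paired(win$ratio, unname(dom_ratio[key]),
                            alternative = alternative),
        error = function(e) NULL)
    }
  }

  tree <- NULL
  if (!is.null(tree_domain)) {
    seqs <- character(0)
    for (g in genes) {
      if (is.na(g$representative)) next
      tx <- g$transcripts[[g$representative]]
      h <- hits[hits$protein_id == tx$id & hits$label == tree_domain, ,
                drop = FALSE]
      for (k in seq_len(nrow(h))) {
        nm <- if (nrow(h) > 1L) paste0(g$id, "/", h$repeat_label[k]) else g$id
        seqs[nm] <- substr(tx$protein, h$start[k] + 1L, h$end[k])
      }
    }
    if (length(seqs) >= 4L) {
      rows <- align_to_reference(seqs)
      tree <- bootstrap_support(rows, n_reps = bootstrap_reps, seed = seed)
    }
  }

  zscores <- NULL
  if (!is.null(tpm)) {
    tab <- if (is.character(tpm))
      as.matrix(read.table(tpm, header = TRUE, sep = "\t", row.names = 1))
    else tpm
    zscores <- zscore_expression(tab)
  }

  manifest <- list(
    package = "mexscan",
    version = as.character(utils::packageVersion("mexscan")),
    seed = seed,
    parameters = list(threshold_nt = threshold_nt,
                      min_overlap_aa = min_overlap_aa,
                      bootstrap_reps = bootstrap_reps,
                      alternative = alternative,
                      accession_map = as.list(accession_map)),
    counts = list(n_genes = length(genes),
                  n_families = sum(families$family != "none"),
                  n_microexons = nrow(micros),
                  n_kaks_rows = if (is.null(kaks_tab)) 0L else nrow(kaks_tab)))

  result <- structure(list(families = families, microexons = micros,
                           summary = summary, kaks = kaks_tab,
                           wilcoxon = wilcox, tree = tree,
                           zscores = zscores, manifest = manifest),
                      class = "mexscan_result")
  if (!is.null(out_dir)) {
    write_report_tables(result, out_dir)
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "tree.nwk"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  result
}
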