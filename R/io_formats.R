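#' @importFrom stats rnorm runif sd setNames pnorm
#' @importFrom utils read.table write.table
NULL

# ---- coordinate convention -------------------------------------------------
# All coordinates inside the package are 0-based, half-open [start, end).
# GFF3 and InterProScan files are 1-based, fully closed; conversion happens
# exactly once, at the I/O boundary.

#' Convert 1-based inclusive coordinates to the internal 0-based half-open form
#'
#' @param start1,end1 integer vectors of 1-based inclusive coordinates
#' @return a list with elements `start` and `end` (0-based half-open)
#' @examples
#' coord_from_1based(100, 151)  # [99, 151), length 52
#' @export
coord_from_1based <- function(start1, end1) {
  if (any(end1 < start1)) stop("interval end < start in 1-based input")
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

#' Convert internal 0-based half-open coordinates back to 1-based inclusive
#'
#' Inverse of [coord_from_1based()].
#' @param start0,end0 integer vectors, 0-based half-open
#' @return a list with elements `start` and `end` (1-based inclusive)
#' @export
coord_to_1based <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

# ---- FASTA -----------------------------------------------------------------

#' Read a (possibly wrapped) multi-record FASTA file
#'
#' Sequences are uppercased and line wrapping is removed. Record ids must be
#' unique within the file.
#'
#' @param path path to a FASTA file
#' @return named character vector, one element per record, in file order
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector
#' @param path output path
#' @param width line-wrap width
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---- GFF3 ------------------------------------------------------------------

#' Read gene/mRNA/exon/CDS features from a GFF3 file
#'
#' Builds an annotation set grouped by parentage. GFF3 1-based inclusive
#' coordinates become 0-based half-open; CDS `phase` is retained. Attributes
#' other than `ID`/`Parent`/phase are ignored.
#'
#' @param path path to a GFF3 file
#' @return an object of class `annotation_set`: a list with data frames
#'   `genes` (gene_id, chrom, start, end, strand), `transcripts`
#'   (transcript_id, gene_id, chrom, strand), `exons` (transcript_id, start,
#'   end) and `cds` (transcript_id, start, end, phase)
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- rtracklayer::readGFF(path,
    columns = c("seqid", "type", "start", "end", "strand", "phase"),
    tags = c("ID", "Parent"))
  g <- as.data.frame(g)
  if (any(g$end < g$start)) stop("GFF3 record with end < start")
  cc <- coord_from_1based(g$start, g$end)
  g$start0 <- cc$start; g$end0 <- cc$end
  # Parent comes back as a list-column (a feature may have several parents)
  parent1 <- vapply(g$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")

  is_gene <- g$type == "gene"
  is_mrna <- g$type %in% c("mRNA", "transcript")
  genes <- data.frame(gene_id = as.character(g$ID[is_gene]),
                      chrom = as.character(g$seqid[is_gene]),
                      start = g$start0[is_gene], end = g$end0[is_gene],
                      strand = as.character(g$strand[is_gene]),
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = as.character(g$ID[is_mrna]),
                            gene_id = parent1[is_mrna],
                            chrom = as.character(g$seqid[is_mrna]),
                            strand = as.character(g$strand[is_mrna]),
                            stringsAsFactors = FALSE)
  if (anyNA(transcripts$gene_id)) stop("mRNA without a parent gene")
  if (!all(transcripts$gene_id %in% genes$gene_id))
    stop("mRNA parent not found among genes: ",
         paste(setdiff(transcripts$gene_id, genes$gene_id), collapse = ", "))

  expand_children <- function(sel) {
    rows <- which(sel)
    if (!length(rows))
      return(data.frame(transcript_id = character(0), start = integer(0),
                        end = integer(0), phase = character(0),
                        stringsAsFactors = FALSE))
    pl <- g$Parent[rows]
    n <- lengths(pl)
    if (any(n == 0L)) stop("exon/CDS feature without a Parent attribute")
    data.frame(transcript_id = unlist(pl, use.names = FALSE),
               start = rep(g$start0[rows], n), end = rep(g$end0[rows], n),
               phase = rep(as.character(g$phase[rows]), n),
               stringsAsFactors = FALSE)
  }
  exons <- expand_children(g$type == "exon")[, c("transcript_id", "start", "end")]
  cds <- expand_children(g$type == "CDS")
  cds$phase[is.na(cds$phase) | cds$phase == "."] <- NA_character_
  cds$phase <- suppressWarnings(as.integer(cds$phase))
  bad <- setdiff(cds$transcript_id, transcripts$transcript_id)
  if (length(bad)) stop("CDS with unresolvable parent mRNA: ", paste(bad, collapse = ", "))

  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, cds = cds),
            class = "annotation_set")
}

# ---- domain-hit table ------------------------------------------------------

#' Default Pfam accession to domain-label map
#'
#' AP2 maps from both PF00847 and PF00876 so that tables produced by either
#' Pfam release vocabulary are accepted; B3 is PF02362, the MADS-box
#' (SRF-type transcription factor) domain is PF00319 and K-box is PF01486.
#' Accessions absent from the map get the label `"other"`.
#' @return named character vector mapping accession to label
#' @export
default_accession_map <- function() {
  c(PF00847 = "AP2", PF00876 = "AP2", PF02362 = "B3",
    PF00319 = "SRF-TF", PF01486 = "K-box")
}

#' Read a per-protein domain-hit table (InterProScan TSV layout)
#'
#' Expects the InterProScan tab-separated layout: protein id (col 1),
#' signature accession (col 5) and 1-based inclusive protein coordinates
#' (cols 7, 8); the other columns are ignored. Coordinates are converted to
#' 0-based half-open. Overlapping hits with the same label on one protein are
#' merged into their union (with a warning), then hits of each label are
#' sorted by start and numbered R1, R2, ... from the N terminus.
#'
#' @param path path to the TSV file
#' @param accession_map named character vector mapping accession to label;
#'   see [default_accession_map()]
#' @return data frame with columns protein_id, accession, label, start, end,
#'   repeat_label
#' @export
read_domain_table <- function(path, accession_map = default_accession_map()) {
  if (!file.exists(path)) stop("domain table not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character", fill = TRUE)
  if (ncol(tab) < 8L) stop("domain table needs at least 8 tab-separated columns")
  s1 <- suppressWarnings(as.integer(tab[[7]]))
  e1 <- suppressWarnings(as.integer(tab[[8]]))
  if (anyNA(s1) || anyNA(e1)) stop("non-numeric domain coordinates")
  cc <- coord_from_1based(s1, e1)
  hits <- data.frame(protein_id = tab[[1]], accession = tab[[5]],
                     label = unname(accession_map[tab[[5]]]),
                     start = cc$start, end = cc$end, stringsAsFactors = FALSE)
  hits$label[is.na(hits$label)] <- "other"
  merge_and_label_hits(hits)
}

# Merge overlapping same-label hits per protein (union), then assign repeat
# labels R1..Rk per (protein, label) by ascending start.
merge_and_label_hits <- function(hits) {
  out <- do.call(rbind, lapply(split(hits, list(hits$protein_id, hits$label), drop = TRUE),
    function(h) {
      h <- h[order(h$start, h$end), , drop = FALSE]
      if (nrow(h) > 1L) {
        keep <- h[1, , drop = FALSE]
        merged <- FALSE
        for (i in 2:nrow(h)) {
          last <- nrow(keep)
          if (h$start[i] < keep$end[last]) {  # overlap -> union
            keep$end[last] <- max(keep$end[last], h$end[i])
            merged <- TRUE
          } else keep <- rbind(keep, h[i, , drop = FALSE])
        }
        if (merged) warning("merged overlapping ", h$label[1], " hits on ",
                            h$protein_id[1])
        h <- keep
      }
      h$repeat_label <- paste0("R", seq_len(nrow(h)))
      h
    }))
  rownames(out) <- NULL
  out[order(out$protein_id, out$start), , drop = FALSE]
}

# ---- newick ----------------------------------------------------------------

#' Write a phylogenetic tree to a newick file
#'
#' Internal-node support values (if present as `node.label`) are emitted as
#' internal node labels; the result round-trips through [ape::read.tree()].
#'
#' @param tree an [ape::phylo] object
#' @param path output path
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate leaf names: ", paste(unique(dup), collapse = ", "))
  ape::write.tree(tree, file = path)
  invisible(path)
}

# ---- report tables ---------------------------------------------------------

# TSV convention for all reports: header row, tab separator, "." for missing.
write_tsv <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2)) {
    v <- df2[[j]]
    if (is.numeric(v)) v <- ifelse(is.na(v), ".", format(v, digits = 10, trim = TRUE))
    else v <- ifelse(is.na(v) | v == "", ".", as.character(v))
    df2[[j]] <- v
  }
  write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the standard report tables of a scan
#'
#' Materializes the per-gene family table, the per-micro-exon table, the
#' overlap summary and (when present) the Ka/Ks pair table as TSV files in
#' `outdir`.
#'
#' @param results a result bundle from [run_scan()]
#' @param outdir output directory (created if missing)
#' @return invisible character vector of files written
#' @export
write_report_tables <- function(results, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  files <- character(0)
  emit <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    files <<- c(files, p)
  }
  emit(results$families, "families.tsv")
  emit(results$microexons, "microexons.tsv")
  emit(results$summary, "overlap_summary.tsv")
  if (!is.null(results$kaks)) emit(results$kaks, "kaks_pairs.tsv")
  invisible(files)
}
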