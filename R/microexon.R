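# Micro-exon calling, domain assignment, positional typing, tandem
# detection and enrichment summaries.
#
# A micro-exon is an exon whose CDS-overlapping portion is 1..threshold nt
# (default 51). The length is measured on the CDS portion only: UTR bases
# cannot overlap a protein domain, so they do not count.

# CDS-offset interval covered by a genomic interval (lo, hi half-open), or
# NULL if no overlap with the CDS.
genomic_interval_to_cds <- function(map, g_start, g_end) {
  g_start <- as.integer(g_start); g_end <- as.integer(g_end)
  bl <- map$blocks
  nts <- c()
  for (k in seq_len(nrow(bl))) {
    o1 <- max(g_start, bl$g_start[k]); o2 <- min(g_end, bl$g_end[k])
    if (o2 <= o1) next
    if (map$strand == "+") {
      nts <- c(nts, bl$cds_start[k] + (o1 - bl$g_start[k]),
               bl$cds_start[k] + (o2 - bl$g_start[k]))
    } else {
      nts <- c(nts, bl$cds_start[k] + (bl$g_end[k] - o2),
               bl$cds_start[k] + (bl$g_end[k] - o1))
    }
  }
  if (is.null(nts)) return(NULL)
  c(min(nts), max(nts))
}

empty_microexon_frame <- function() {
  data.frame(gene_id = character(0), transcript_id = character(0),
             exon_index = integer(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             coding_length = integer(0), cds_start = integer(0),
             cds_end = integer(0), res_start = integer(0),
             res_end = integer(0), start_partial = logical(0),
             end_partial = logical(0), domain_label = character(0),
             domain_start = integer(0), domain_end = integer(0),
             type_label = character(0), tandem_group = character(0),
             stringsAsFactors = FALSE)
}

#' Call micro-exons on the representative transcript of a gene
#'
#' One record per exon whose CDS-overlapping portion has length in
#' `[1, threshold_nt]`. Exons with no CDS overlap (pure UTR) are skipped.
#' Genomic coordinates of the record cover the coding portion of the exon.
#'
#' @param gene a gene model from [assemble_transcripts()]
#' @param threshold_nt maximum coding length in nucleotides (default 51)
#' @return data frame of micro-exons (possibly zero rows); columns include
#'   gene/transcript ids, 0-based `exon_index` in transcript orientation,
#'   genomic interval, `coding_length`, CDS offsets, residue interval with
#'   partial-codon flags, and placeholder `domain_label`/`type_label`/
#'   `tandem_group` columns
#' @export
call_microexons <- function(gene, threshold_nt = 51L) {
  out <- empty_microexon_frame()
  rep_id <- gene$representative
  if (is.na(rep_id)) return(out)
  tx <- gene$transcripts[[rep_id]]
  if (!isTRUE(tx$valid)) return(out)
  map <- build_coordinate_map(tx)
  ex <- tx$exons
  cd <- tx$cds
  for (i in seq_len(nrow(ex))) {
    o1 <- pmax(ex$start[i], cd$start); o2 <- pmin(ex$end[i], cd$end)
    len <- sum(pmax(0L, o2 - o1))
    if (len < 1L || len > threshold_nt) next
    gs <- min(o1[o2 > o1]); ge <- max(o2[o2 > o1])
    cc <- genomic_interval_to_cds(map, gs, ge)
    if (is.null(cc)) next  # coding bases all inside the phase trim
    res <- genomic_interval_to_protein(map, gs, ge)
    out <- rbind(out, data.frame(
      gene_id = gene$id, transcript_id = tx$id, exon_index = i - 1L,
      chrom = tx$chrom, start = gs, end = ge, strand = tx$strand,
      coding_length = len, cds_start = cc[1], cds_end = cc[2],
      res_start = res$res_start, res_end = res$res_end,
      start_partial = res$start_partial, end_partial = res$end_partial,
      domain_label = NA_character_, domain_start = NA_integer_,
      domain_end = NA_integer_, type_label = NA_character_,
      tandem_group = NA_character_, stringsAsFactors = FALSE))
  }
  out
}

#' Assign each micro-exon to the protein domain it overlaps
#'
#' The residue interval of the micro-exon (closed over partial codons) is
#' intersected with each domain hit of the representative protein; the hit
#' with the largest overlap (>= `min_overlap_aa` residues) wins, ties going
#' to the N-terminal-most hit. AP2 hits carry their repeat label
#' (`"AP2/R1"`, `"AP2/R2"`), SRF-TF hits become `"MADS-box"`; a micro-exon
#' overlapping nothing is labelled `"none"`.
#'
#' @param micros micro-exon data frame from [call_microexons()]
#' @param hits domain-hit data frame from [read_domain_table()] (any
#'   proteins; matched on `transcript_id == protein_id`)
#' @param min_overlap_aa minimum residue overlap (default 1)
#' @return `micros` with `domain_label`, `domain_start`, `domain_end` filled
#' @export
assign_domain <- function(micros, hits, min_overlap_aa = 1L) {
  if (nrow(micros) == 0L) return(micros)
  for (i in seq_len(nrow(micros))) {
    h <- hits[hits$protein_id == micros$transcript_id[i], , drop = FALSE]
    micros$domain_label[i] <- "none"
    if (nrow(h) == 0L) next
    ov <- pmin(h$end, micros$res_end[i]) - pmax(h$start, micros$res_start[i])
    ok <- which(ov >= min_overlap_aa)
    if (!length(ok)) next
    best <- ok[order(-ov[ok], h$start[ok])][1]
    lab <- h$label[best]
    micros$domain_label[i] <- switch(lab,
      "AP2" = paste0("AP2/", h$repeat_label[best]),
      "SRF-TF" = "MADS-box",
      lab)
    micros$domain_start[i] <- h$start[best]
    micros$domain_end[i] <- h$end[best]
  }
  micros
}

#' Default micro-exon type configuration
#'
#' The four recurrent AP2-domain micro-exon classes: 9, 26 and 31 nt inside
#' the first AP2 repeat (R1M1, R1M2, R1M3) and 45 nt inside the second
#' (R2M1). Position class `"any"` places no positional constraint.
#'
#' @return data frame with columns name, context, length_nt, position
#' @export
default_type_config <- function() {
  data.frame(name = c("R1M1", "R1M2", "R1M3", "R2M1"),
             context = c("AP2/R1", "AP2/R1", "AP2/R1", "AP2/R2"),
             length_nt = c(9L, 26L, 31L, 45L),
             position = "any", stringsAsFactors = FALSE)
}

match_position <- function(pos, res_start, res_end, dom_start, dom_end,
                           margin = 2L) {
  switch(pos,
    any = TRUE,
    `N-terminal` = !is.na(dom_start) && res_start <= dom_start + margin,
    `C-terminal` = !is.na(dom_end) && res_end >= dom_end - margin,
    internal = !is.na(dom_start) && res_start > dom_start + margin &&
      res_end < dom_end - margin,
    stop("unknown position class: ", pos))
}

#' Classify micro-exons into named types
#'
#' A micro-exon gets the name of the unique configuration row matching its
#' domain context, exact coding length and position class; no match gives
#' `"unclassified"`, more than one is a configuration error.
#'
#' @param micros micro-exon data frame after [assign_domain()]
#' @param config a type configuration, see [default_type_config()]
#' @return `micros` with `type_label` filled
#' @export
classify_type <- function(micros, config = default_type_config()) {
  if (anyDuplicated(config$name)) stop("duplicate type names in configuration")
  if (nrow(micros) == 0L) return(micros)
  for (i in seq_len(nrow(micros))) {
    hitrows <- which(config$context == micros$domain_label[i] &
                     config$length_nt == micros$coding_length[i])
    hitrows <- hitrows[vapply(hitrows, function(r) {
      match_position(config$position[r], micros$res_start[i],
                     micros$res_end[i], micros$domain_start[i],
                     micros$domain_end[i])
    }, TRUE)]
    if (length(hitrows) > 1L)
      stop("type configuration ambiguous for micro-exon in ",
           micros$gene_id[i], ": ", paste(config$name[hitrows], collapse = ", "))
    micros$type_label[i] <- if (length(hitrows) == 1L) config$name[hitrows]
                            else "unclassified"
  }
  micros
}

#' Detect tandem micro-exon groups
#'
#' A tandem group is a maximal run of micro-exons at consecutive exon indices
#' of one transcript, of size >= 2. Members of a K-box-context tandem are
#' additionally typed M1, M2, ... from 5' to 3', the arrangement typical of
#' the C-terminal region of the K-box domain.
#'
#' @param micros micro-exon data frame (any number of transcripts)
#' @return `micros` with `tandem_group` (transcript-scoped ids "T1", "T2",
#'   ...) filled, and `type_label` set to M1/M2/... for K-box tandems
#' @export
detect_tandem <- function(micros) {
  if (nrow(micros) == 0L) return(micros)
  for (tid in unique(micros$transcript_id)) {
    sel <- which(micros$transcript_id == tid)
    sel <- sel[order(micros$exon_index[sel])]
    idx <- micros$exon_index[sel]
    run_id <- cumsum(c(1L, diff(idx) != 1L))
    gnum <- 0L
    for (r in unique(run_id)) {
      members <- sel[run_id == r]
      if (length(members) < 2L) next
      gnum <- gnum + 1L
      micros$tandem_group[members] <- paste0("T", gnum)
      if (any(micros$domain_label[members] == "K-box", na.rm = TRUE))
        micros$type_label[members] <- paste0("M", seq_along(members))
    }
  }
  micros
}

#' Summarize micro-exon / domain overlap per gene family
#'
#' Reports, for each family, how many micro-exons of that family's genes
#' fall inside the family's hallmark domain (AP2 for AP2/ERF, K-box for
#' MIKC), plus a genome-wide row counting micro-exons inside any domain.
#' Empty groups report a missing fraction, not 0.
#'
#' @param micros micro-exon data frame after [assign_domain()]
#' @param families family-assignment data frame from [classify_families()]
#' @return data frame with columns group, domain, n_microexons, n_in_domain,
#'   fraction
#' @export
summarize_overlap <- function(micros, families) {
  fam_of <- setNames(families$family, families$gene_id)
  fam <- fam_of[micros$gene_id]
  row_for <- function(group, domain, keep, inside) {
    n <- sum(keep)
    k <- sum(keep & inside)
    data.frame(group = group, domain = domain, n_microexons = n,
               n_in_domain = k,
               fraction = if (n > 0L) k / n else NA_real_,
               stringsAsFactors = FALSE)
  }
  in_ap2 <- !is.na(micros$domain_label) & startsWith(micros$domain_label, "AP2")
  in_kbox <- !is.na(micros$domain_label) & micros$domain_label == "K-box"
  in_any <- !is.na(micros$domain_label) & micros$domain_label != "none"
  rbind(
    row_for("AP2/ERF", "AP2", !is.na(fam) & fam == "AP2/ERF", in_ap2),
    row_for("MIKC", "K-box", !is.na(fam) & fam == "MIKC", in_kbox),
    row_for("all", "any", rep(TRUE, nrow(micros)), in_any))
}
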