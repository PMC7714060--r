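# Gene-family assignment from Pfam-style domain architectures, on the
# representative isoform only.
#
# AP2/ERF subfamilies follow the domain-count rules used throughout the
# plant transcription-factor literature: >= 2 AP2 domains -> AP2 subfamily;
# 1 AP2 + B3 -> RAV; 1 AP2 + any other labelled domain -> "other";
# a lone AP2 -> ERF/DREB. MIKC-type MADS-box genes require both an SRF-TF
# (MADS-box) domain and a K-box domain; SRF-TF alone (type I) is excluded.

#' Classify one protein's AP2/ERF subfamily from its domain hits
#'
#' Rules, in priority order: >= 2 AP2 hits -> subfamily "AP2"; 1 AP2 and
#' >= 1 B3 -> "RAV"; 1 AP2 and >= 1 other labelled non-AP2/non-B3 domain ->
#' "other"; exactly 1 AP2 alone -> "ERF/DREB"; no AP2 -> family "none".
#'
#' @param hits domain-hit data frame rows for one protein
#' @return list with `family`, `subfamily` and `evidence` (the hits)
#' @export
classify_ap2_erf <- function(hits) {
  n_ap2 <- sum(hits$label == "AP2")
  n_b3 <- sum(hits$label == "B3")
  n_other <- sum(!hits$label %in% c("AP2", "B3"))
  if (n_ap2 == 0L)
    return(list(family = "none", subfamily = NA_character_,
                evidence = hits[0, , drop = FALSE]))
  subfam <-
    if (n_ap2 >= 2L) "AP2"
    else if (n_b3 >= 1L) "RAV"
    else if (n_other >= 1L) "other"
    else "ERF/DREB"
  list(family = "AP2/ERF", subfamily = subfam, evidence = hits)
}

#' Identify a MIKC-type MADS-box protein from its domain hits
#'
#' MIKC requires at least one SRF-TF (MADS-box) hit and at least one K-box
#' hit; either alone gives family "none".
#'
#' @param hits domain-hit data frame rows for one protein
#' @return list with `family` ("MIKC" or "none"), `subfamily` (NA) and
#'   `evidence`
#' @export
identify_mikc <- function(hits) {
  has <- sum(hits$label == "SRF-TF") >= 1L && sum(hits$label == "K-box") >= 1L
  list(family = if (has) "MIKC" else "none", subfamily = NA_character_,
       evidence = if (has) hits[hits$label %in% c("SRF-TF", "K-box"), ,
                               drop = FALSE]
                  else hits[0, , drop = FALSE])
}

#' Relabel the AP2 repeats of an AP2-subfamily protein R1, R2, ... by position
#'
#' Repeats are numbered by ascending protein start, i.e. from the N terminus
#' to the C terminus. A no-op for other subfamilies.
#'
#' @param assignment a list from [classify_ap2_erf()]
#' @return the assignment with AP2 evidence hits renumbered
#' @export
label_ap2_repeats <- function(assignment) {
  if (!identical(assignment$subfamily, "AP2")) return(assignment)
  ev <- assignment$evidence
  ap2 <- which(ev$label == "AP2")
  ev$repeat_label[ap2[order(ev$start[ap2])]] <- paste0("R", seq_along(ap2))
  assignment$evidence <- ev
  assignment
}

#' Assign a family and subfamily to every gene
#'
#' Runs the AP2/ERF rules first; genes without an AP2 domain are then tested
#' against the MIKC architecture. Only the representative isoform's hits are
#' considered.
#'
#' @param genes list of gene models from [assemble_transcripts()]
#' @param hits domain-hit data frame from [read_domain_table()]
#' @return data frame: gene_id, family, subfamily, n_AP2, n_B3, n_SRF_TF,
#'   n_K_box
#' @export
classify_families <- function(genes, hits) {
  rows <- lapply(genes, function(g) {
    rep_id <- g$representative
    h <- if (is.na(rep_id)) hits[0, , drop = FALSE]
         else hits[hits$protein_id == rep_id, , drop = FALSE]
    a <- classify_ap2_erf(h)
    if (a$family == "none") a <- identify_mikc(h)
    data.frame(gene_id = g$id, family = a$family,
               subfamily = a$subfamily,
               n_AP2 = sum(h$label == "AP2"), n_B3 = sum(h$label == "B3"),
               n_SRF_TF = sum(h$label == "SRF-TF"),
               n_K_box = sum(h$label == "K-box"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
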