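# Transcript models, representative-isoform selection, CDS splicing and
# translation, and projection among genomic / CDS / protein coordinate spaces.
# Exons and CDS segments are kept in transcript (5'->3') orientation:
# ascending genomic start on "+", descending on "-".

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Assemble gene models from an annotation set
#'
#' Orders exons and CDS segments 5'->3' in transcript orientation, splices and
#' translates each CDS against the genome, flags invalid transcripts (CDS
#' outside exons, length not a multiple of 3 after phase trimming, internal
#' stop codons) and selects the representative isoform of each gene.
#'
#' @param annotation an `annotation_set` from [read_gff3()]
#' @param genome named character vector of chromosome sequences
#'   (from [read_fasta()])
#' @return list of gene models; each is a list with `id`, `transcripts`
#'   (each with `id`, `gene_id`, `chrom`, `strand`, `exons`, `cds`,
#'   `cds_seq`, `protein`, `valid`) and `representative` (a transcript id,
#'   or `NA` if the gene has no valid coding transcript)
#' @export
assemble_transcripts <- function(annotation, genome) {
  stopifnot(inherits(annotation, "annotation_set"))
  tx_split_ex <- split(annotation$exons, annotation$exons$transcript_id)
  tx_split_cds <- split(annotation$cds, annotation$cds$transcript_id)

  genes <- lapply(split(annotation$transcripts, annotation$transcripts$gene_id),
    function(txs) {
      models <- lapply(seq_len(nrow(txs)), function(i) {
        tid <- txs$transcript_id[i]
        strand <- txs$strand[i]
        ex <- tx_split_ex[[tid]]
        cd <- tx_split_cds[[tid]]
        ord <- function(df) {
          if (is.null(df) || nrow(df) == 0L) return(df)
          df[order(df$start, decreasing = (strand == "-")), , drop = FALSE]
        }
        ex <- ord(ex); cd <- ord(cd)
        tm <- list(id = tid, gene_id = txs$gene_id[i], chrom = txs$chrom[i],
                   strand = strand, exons = ex, cds = cd,
                   cds_seq = "", protein = "", valid = FALSE)
        if (is.null(cd) || nrow(cd) == 0L) {
          tm$valid <- FALSE  # non-coding; retained but never representative
          return(tm)
        }
        contained <- vapply(seq_len(nrow(cd)), function(k) {
          any(ex$start <= cd$start[k] & cd$end[k] <= ex$end)
        }, TRUE)
        if (!all(contained)) {
          warning("transcript ", tid, ": CDS segment outside exons; excluded")
          return(tm)
        }
        cds_seq <- tryCatch(splice_cds(tm, genome), error = function(e) {
          warning("transcript ", tid, ": ", conditionMessage(e)); NULL
        })
        if (is.null(cds_seq) || nchar(cds_seq) %% 3L != 0L) {
          if (!is.null(cds_seq))
            warning("transcript ", tid, ": CDS length not a multiple of 3; excluded")
          return(tm)
        }
        prot <- translate_cds(cds_seq)
        if (grepl("*", prot, fixed = TRUE)) {
          warning("transcript ", tid, ": internal stop codon; excluded")
          return(tm)
        }
        tm$cds_seq <- cds_seq; tm$protein <- prot; tm$valid <- TRUE
        tm
      })
      names(models) <- vapply(models, `[[`, "", "id")
      gm <- list(id = txs$gene_id[1], transcripts = models,
                 representative = NA_character_)
      rep_id <- tryCatch(select_representative(gm), error = function(e) {
        warning(conditionMessage(e)); NA_character_
      })
      gm$representative <- rep_id
      gm
    })
  genes[order(names(genes))]
}

#' Select the representative isoform of a gene: the longest protein
#'
#' Ties are broken by the lexicographically smallest transcript id so the
#' choice is deterministic across runs.
#'
#' @param gene a gene model from [assemble_transcripts()]
#' @return the chosen transcript id
#' @export
select_representative <- function(gene) {
  valid <- Filter(function(t) isTRUE(t$valid), gene$transcripts)
  if (length(valid) == 0L)
    stop("gene ", gene$id, ": no valid coding transcript; excluded")
  lens <- vapply(valid, function(t) nchar(t$protein), 0L)
  ids <- vapply(valid, `[[`, "", "id")
  best <- ids[lens == max(lens)]
  unname(sort(best)[1])
}

#' Splice the CDS of a transcript out of the genome
#'
#' Concatenates CDS segments 5'->3' in transcript orientation (reverse
#' complemented on the "-" strand) and trims leading bases according to the
#' phase of the first segment. Missing phases (".") are treated as 0.
#'
#' @param transcript a transcript model
#' @param genome named character vector of chromosome sequences
#' @return the spliced CDS nucleotide string
#' @export
splice_cds <- function(transcript, genome) {
  cd <- transcript$cds
  chrom <- transcript$chrom
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  seq <- genome[[chrom]]
  if (any(cd$start < 0L) || any(cd$end > nchar(seq)))
    stop("CDS segment out of chromosome bounds on ", chrom)
  pieces <- substring(seq, cd$start + 1L, cd$end)  # 0-based half-open -> substring
  if (transcript$strand == "-") pieces <- vapply(pieces, revcomp, "")
  cds <- paste0(pieces, collapse = "")
  phase <- cd$phase[1]
  if (is.na(phase)) phase <- 0L
  if (phase > 0L) cds <- substring(cds, phase + 1L)
  cds
}

#' Translate a CDS under the standard genetic code
#'
#' A single trailing stop codon is trimmed. Codons containing ambiguous bases
#' translate to "X". Internal stops are retained as "*" in the returned
#' string; callers treat their presence as an invalid transcript.
#'
#' @param cds nucleotide string, length a multiple of 3
#' @return amino-acid string
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) stop("CDS length not a multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  sub("\\*$", "", aa)
}

#' Build the CDS coordinate map of a transcript
#'
#' Pairs genomic intervals with contiguous CDS-offset intervals after phase
#' trimming. Within a "+" block CDS offset `cs + i` maps to genomic
#' `g_start + i`; within a "-" block it maps to `g_end - 1 - i`.
#'
#' @param transcript a valid transcript model
#' @return object of class `cds_map`: list with `transcript_id`, `chrom`,
#'   `strand`, `cds_length` and `blocks` (data frame cds_start, cds_end,
#'   g_start, g_end)
#' @export
build_coordinate_map <- function(transcript) {
  cd <- transcript$cds
  phase <- cd$phase[1]
  if (is.na(phase)) phase <- 0L
  g_start <- cd$start; g_end <- cd$end
  if (phase > 0L) {
    if (transcript$strand == "+") g_start[1] <- g_start[1] + phase
    else g_end[1] <- g_end[1] - phase
  }
  lens <- g_end - g_start
  cds_end <- cumsum(lens)
  blocks <- data.frame(cds_start = cds_end - lens, cds_end = cds_end,
                       g_start = g_start, g_end = g_end)
  structure(list(transcript_id = transcript$id, chrom = transcript$chrom,
                 strand = transcript$strand, cds_length = sum(lens),
                 blocks = blocks),
            class = "cds_map")
}

# Map a CDS-offset interval [a, b) to genomic blocks (transcript order).
cds_interval_to_genomic <- function(map, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  bl <- map$blocks
  out <- list()
  for (k in seq_len(nrow(bl))) {
    o1 <- max(a, bl$cds_start[k]); o2 <- min(b, bl$cds_end[k])
    if (o2 <= o1) next
    if (map$strand == "+") {
      gs <- bl$g_start[k] + (o1 - bl$cds_start[k])
      ge <- bl$g_start[k] + (o2 - bl$cds_start[k])
    } else {
      ge <- bl$g_end[k] - (o1 - bl$cds_start[k])
      gs <- bl$g_end[k] - (o2 - bl$cds_start[k])
    }
    out[[length(out) + 1L]] <- data.frame(chrom = map$chrom, start = gs,
                                          end = ge, strand = map$strand)
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0)))
  do.call(rbind, out)
}

#' Project a protein residue interval to genomic intervals
#'
#' @param map a `cds_map` from [build_coordinate_map()]
#' @param res_start,res_end residue interval, 0-based half-open
#' @return data frame of genomic blocks (chrom, start, end, strand) in
#'   transcript order; total length is `3 * (res_end - res_start)`
#' @export
protein_interval_to_genomic <- function(map, res_start, res_end) {
  res_start <- as.integer(res_start); res_end <- as.integer(res_end)
  stopifnot(res_end > res_start, res_start >= 0)
  if (3L * res_end > map$cds_length)
    stop("residue interval beyond protein length")
  cds_interval_to_genomic(map, 3L * res_start, 3L * res_end)
}

#' Project a genomic interval to the covering protein residue interval
#'
#' Returns the smallest residue interval whose codons intersect the genomic
#' interval, with flags marking partial codons at either end.
#'
#' @param map a `cds_map`
#' @param g_start,g_end genomic interval, 0-based half-open
#' @return list with `res_start`, `res_end` (0-based half-open),
#'   `start_partial`, `end_partial`; or `NULL` when the interval does not
#'   intersect the CDS
#' @export
genomic_interval_to_protein <- function(map, g_start, g_end) {
  g_start <- as.integer(g_start); g_end <- as.integer(g_end)
  bl <- map$blocks
  nts <- c()
  for (k in seq_len(nrow(bl))) {
    o1 <- max(g_start, bl$g_start[k]); o2 <- min(g_end, bl$g_end[k])
    if (o2 <= o1) next
    if (map$strand == "+") {
      c1 <- bl$cds_start[k] + (o1 - bl$g_start[k])
      c2 <- bl$cds_start[k] + (o2 - bl$g_start[k])
    } else {
      c1 <- bl$cds_start[k] + (bl$g_end[k] - o2)
      c2 <- bl$cds_start[k] + (bl$g_end[k] - o1)
    }
    nts <- c(nts, c1, c2)
  }
  if (is.null(nts)) return(NULL)
  lo <- min(nts); hi <- max(nts)  # CDS nt interval [lo, hi)
  list(res_start = lo %/% 3L, res_end = (hi - 1L) %/% 3L + 1L,
       start_partial = (lo %% 3L) != 0L, end_partial = (hi %% 3L) != 0L)
}
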