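# Pairwise protein alignment with codon back-threading, Nei-Gojobori (NG86)
# Ka/Ks with Jukes-Cantor correction, exact/approximate Wilcoxon signed-rank
# comparison, Poisson-corrected distances and Saitou-Nei neighbor joining
# with column-resampling bootstrap.

.mexscan_cache <- new.env(parent = emptyenv())

genetic_code <- function() Biostrings::GENETIC_CODE

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

#' The BLOSUM62 substitution matrix
#'
#' Cached copy of the BLOSUM62 matrix shipped with Biostrings, the default
#' scoring table for [align_proteins()].
#' @return integer matrix with amino-acid dimnames
#' @export
blosum62 <- function() {
  if (is.null(.mexscan_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mexscan_cache$blosum62 <- e$BLOSUM62
  }
  .mexscan_cache$blosum62
}

# ---- NG86 site and difference counting -------------------------------------

codon_mutants <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (pos in 1:3) {
    for (b in setdiff(bases, substr(codon, pos, pos))) {
      m <- codon
      substr(m, pos, pos) <- b
      out <- c(out, m)
    }
  }
  out
}

#' NG86 synonymous/nonsynonymous site counts of one codon
#'
#' For each of the three positions, the synonymous fraction is the number of
#' synonymous single-nucleotide changes divided by the number of changes not
#' creating a stop codon (stop-creating mutations are excluded from both
#' numerator and denominator). `s` sums these fractions and `n = 3 - s`.
#'
#' @param codon a sense codon over \{A,C,G,T\}
#' @return numeric vector `c(s, n)`
#' @export
ng86_sites <- function(codon) {
  gc <- genetic_code()
  codon <- toupper(codon)
  if (!codon %in% names(gc)) stop("not a valid codon: ", codon)
  if (gc[[codon]] == "*") stop("stop codon has no NG86 sites: ", codon)
  aa <- gc[[codon]]
  s <- 0
  bases <- c("A", "C", "G", "T")
  for (pos in 1:3) {
    muts <- vapply(setdiff(bases, substr(codon, pos, pos)), function(b) {
      m <- codon; substr(m, pos, pos) <- b; m
    }, "")
    aas <- gc[muts]
    keep <- aas != "*"
    if (any(keep)) s <- s + sum(aas[keep] == aa) / sum(keep)
  }
  c(s = s, n = 3 - s)
}

#' NG86 synonymous/nonsynonymous differences between two codons
#'
#' Averages per-step synonymous/nonsynonymous counts over all minimal
#' mutational pathways between the codons (1, 2 or 6 orderings for 1, 2 or 3
#' differing positions). Pathways passing through a stop codon are excluded
#' from the average; in the degenerate case where every pathway is blocked,
#' all pathways are used with steps into/out of stops counted as
#' nonsynonymous.
#'
#' @param codon_a,codon_b sense codons over \{A,C,G,T\}
#' @return numeric vector `c(sd, nd)`
#' @export
ng86_differences <- function(codon_a, codon_b) {
  gc <- genetic_code()
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (c0 in c(codon_a, codon_b)) {
    if (!c0 %in% names(gc)) stop("not a valid codon: ", c0)
    if (gc[[c0]] == "*") stop("stop codon in NG86 difference counting: ", c0)
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  if (length(diff_pos) == 0L) return(c(sd = 0, nd = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  paths <- perms(diff_pos)
  walk <- function(order_) {
    cur <- codon_a
    sd <- 0; nd <- 0; blocked <- FALSE
    for (pos in order_) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (gc[[nxt]] == "*") blocked <- TRUE
      if (!blocked && gc[[nxt]] == gc[[cur]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    list(sd = sd, nd = nd, blocked = blocked)
  }
  res <- lapply(paths, walk)
  ok <- !vapply(res, `[[`, TRUE, "blocked")
  use <- if (any(ok)) res[ok] else res
  c(sd = mean(vapply(use, `[[`, 0, "sd")),
    nd = mean(vapply(use, `[[`, 0, "nd")))
}

# Lazy lookup tables over all sense codons: per-codon site counts and
# pairwise difference counts. Makes kaks() a table lookup.
ng86_tables <- function() {
  if (is.null(.mexscan_cache$ng86)) {
    sc <- sense_codons()
    sites <- t(vapply(sc, ng86_sites, c(s = 0, n = 0)))
    n <- length(sc)
    sd_mat <- matrix(0, n, n, dimnames = list(sc, sc))
    nd_mat <- sd_mat
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i < j) next
      d <- ng86_differences(sc[i], sc[j])
      sd_mat[i, j] <- sd_mat[j, i] <- d[["sd"]]
      nd_mat[i, j] <- nd_mat[j, i] <- d[["nd"]]
    }
    .mexscan_cache$ng86 <- list(sites = sites, sd = sd_mat, nd = nd_mat)
  }
  .mexscan_cache$ng86
}

# ---- codon alignments and Ka/Ks --------------------------------------------

#' Optimal global protein alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length k costs `gap_open + k * gap_extend`. Traceback ties are
#' broken deterministically: diagonal, then up (gap in `b`), then left
#' (gap in `a`).
#'
#' @param a,b amino-acid strings
#' @param substitution scoring matrix (default [blosum62()])
#' @param gap_open,gap_extend gap penalties (positive numbers)
#' @return list with `a`, `b` (aligned strings with "-" gaps), `score`
#' @export
align_proteins <- function(a, b, substitution = blosum62(),
                           gap_open = 10, gap_extend = 1) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  bad <- setdiff(unique(c(av, bv)), rownames(substitution))
  if (length(bad)) stop("invalid residue(s): ", paste(bad, collapse = ", "))
  n <- length(av); m <- length(bv)
  go <- gap_open + gap_extend  # cost of a length-1 gap
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + i * gap_extend)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + j * gap_extend)
  S <- substitution[av, bv, drop = FALSE]
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1, j + 1] <- max(M[i, j + 1] - go, X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - go)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - go, Y[i + 1, j] - gap_extend,
                             X[i + 1, j] - go)
    }
  }
  # traceback; preference order at ties: diagonal (M), up (X), left (Y)
  i <- n; j <- m
  state <- which.max(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  score <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])[state]
  ra <- character(0); rb <- character(0)
  while (i > 0 || j > 0) {
    if (state == 1L) {
      ra <- c(av[i], ra); rb <- c(bv[j], rb)
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1; j <- j - 1
      state <- which.max(prev)
    } else if (state == 2L) {  # up: consume a, gap in b
      ra <- c(av[i], ra); rb <- c("-", rb)
      val <- X[i + 1, j + 1]
      cand <- c(M[i, j + 1] - go, X[i, j + 1] - gap_extend, Y[i, j + 1] - go)
      i <- i - 1
      state <- which.max(abs(cand - val) < 1e-9)
    } else {  # left: consume b, gap in a
      ra <- c("-", ra); rb <- c(bv[j], rb)
      val <- Y[i + 1, j + 1]
      cand <- c(M[i + 1, j] - go, Y[i + 1, j] - gap_extend, X[i + 1, j] - go)
      j <- j - 1
      state <- c(1L, 3L, 2L)[which.max(abs(cand - val) < 1e-9)]
    }
    if (i == 0 && j > 0) state <- 3L
    if (j == 0 && i > 0) state <- 2L
  }
  list(a = paste0(ra, collapse = ""), b = paste0(rb, collapse = ""),
       score = score)
}

#' Thread coding sequences through a protein alignment
#'
#' Replaces each aligned residue by its codon; gap columns become `"---"`.
#' Each CDS must be exactly 3x its protein's ungapped length and translate
#' back to it.
#'
#' @param aln a pairwise alignment from [align_proteins()]
#' @param cds_a,cds_b in-frame coding sequences (no stop) for the two proteins
#' @return list of class `codon_alignment` with `codons_a`, `codons_b`
#'   (vectors of triplets / `"---"`) and the input ids if present
#' @export
thread_codons <- function(aln, cds_a, cds_b) {
  thread_one <- function(aligned, cds, who) {
    res <- strsplit(aligned, "")[[1]]
    prot <- res[res != "-"]
    if (nchar(cds) != 3L * length(prot))
      stop("cds_", who, " length is not 3x the ungapped protein length")
    tr <- strsplit(translate_cds(cds), "")[[1]]
    bad <- which(tr != prot)
    if (length(bad))
      stop("cds_", who, " translation mismatch at residue ", bad[1],
           " (", tr[bad[1]], " vs ", prot[bad[1]], ")")
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    out <- rep("---", length(res))
    out[res != "-"] <- codons
    out
  }
  structure(list(codons_a = thread_one(aln$a, cds_a, "a"),
                 codons_b = thread_one(aln$b, cds_b, "b")),
            class = "codon_alignment")
}

normalize_region <- function(region, ncol_aln) {
  if (is.null(region)) return(seq_len(ncol_aln))
  if (is.list(region) || is.matrix(region)) {
    if (is.matrix(region)) region <- split(region, row(region))
    cols <- unlist(lapply(region, function(r) seq(r[1] + 1L, r[2])))
    return(sort(unique(cols)))
  }
  stopifnot(length(region) == 2L, region[2] > region[1])
  seq(region[1] + 1L, region[2])  # 0-based half-open -> 1-based columns
}

#' NG86 Ka/Ks on a codon alignment, optionally restricted to a region
#'
#' Comparable columns are those where both codons are ungapped sense codons
#' over \{A,C,G,T\}; everything else (gaps, ambiguous bases, stops) is
#' skipped, i.e. complete-codon deletion. Site counts S and N are the means
#' of the two sequences' per-codon NG86 sites summed over comparable
#' columns; Sd and Nd sum pathway-averaged differences. `ps = Sd/S` and
#' `pn = Nd/N` are Jukes-Cantor corrected, `Ks = -(3/4) log(1 - (4/3) ps)`
#' (and likewise Ka); the ratio is `NA` when Ks is 0 or a correction is
#' undefined (p >= 3/4).
#'
#' @param caln a `codon_alignment` from [thread_codons()]
#' @param region optional region: a length-2 vector (0-based half-open
#'   alignment-column interval) or a list of such intervals (their union)
#' @return list of class `kaks_result`: S, N, Sd, Nd, ps, pn, Ka, Ks,
#'   ratio, n_codons
#' @export
kaks <- function(caln, region = NULL) {
  tabs <- ng86_tables()
  cols <- normalize_region(region, length(caln$codons_a))
  ca <- caln$codons_a[cols]; cb <- caln$codons_b[cols]
  ok <- ca %in% rownames(tabs$sites) & cb %in% rownames(tabs$sites)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0L) stop("no comparable codon columns in region")
  S <- (sum(tabs$sites[ca, "s"]) + sum(tabs$sites[cb, "s"])) / 2
  N <- (sum(tabs$sites[ca, "n"]) + sum(tabs$sites[cb, "n"])) / 2
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -(3 / 4) * log(1 - (4 / 3) * p)
  }
  Ks <- jc(ps); Ka <- jc(pn)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
                 Ka = Ka, Ks = Ks, ratio = ratio, n_codons = length(ca)),
            class = "kaks_result")
}

# ---- Wilcoxon signed-rank --------------------------------------------------

#' Paired one-sided Wilcoxon signed-rank comparison of Ka/Ks ratios
#'
#' Pairs with a missing value and zero differences are dropped (counts
#' reported). For `n_used <= 25` the p-value comes from the exact signed-rank
#' distribution (a generating-function convolution over the midranks, so ties
#' are handled exactly); above that a normal approximation with continuity
#' and tie corrections is used.
#'
#' @param ratios_region,ratios_domain equal-length numeric vectors of paired
#'   ratios (e.g. micro-exon window vs whole domain)
#' @param alternative "greater" (region exceeds domain) or "less"
#' @return list of class `signed_rank_test`: statistic `W`, `n_used`,
#'   `n_zero_dropped`, `n_na_dropped`, `p_value`, `alternative`, `method`
#' @export
compare_kaks_paired <- function(ratios_region, ratios_domain,
                                alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(ratios_region) != length(ratios_domain))
    stop("paired vectors must have equal length")
  ok <- !(is.na(ratios_region) | is.na(ratios_domain))
  n_na <- sum(!ok)
  d <- ratios_region[ok] - ratios_domain[ok]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("no usable pairs after dropping missing and zero differences")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 25L) {
    # exact null: convolve (1 + x^(2r_i))/2 over integerized (doubled) ranks
    r2 <- as.integer(round(2 * r))
    tot <- sum(r2)
    f <- numeric(tot + 1L); f[1] <- 1
    for (ri in r2) {
      g <- numeric(tot + 1L)
      g[seq_len(tot + 1L - ri) + ri] <- f[seq_len(tot + 1L - ri)]
      f <- (f + g) / 2
    }
    w2 <- as.integer(round(2 * W))
    p <- if (alternative == "greater") sum(f[(w2 + 1L):(tot + 1L)])
         else sum(f[1:(w2 + 1L)])
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- if (alternative == "greater") (W - mu - 0.5) / sqrt(sigma2)
         else (W - mu + 0.5) / sqrt(sigma2)
    p <- if (alternative == "greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- "normal approximation"
  }
  structure(list(statistic = W, n_used = n, n_zero_dropped = n_zero,
                 n_na_dropped = n_na, p_value = min(1, p),
                 alternative = alternative, method = method),
            class = "signed_rank_test")
}

# ---- distances, NJ, bootstrap ----------------------------------------------

#' Poisson-corrected distance between two aligned protein rows
#'
#' `p` is the mismatch fraction over columns where both rows are ungapped;
#' the distance is `-log(1 - p)`. A fully divergent pair (`p = 1`) is
#' flagged saturated and set to `cap`.
#'
#' @param a,b equal-length aligned strings
#' @param cap distance assigned to saturated pairs (default 10)
#' @return numeric distance, with attribute `saturated`
#' @export
poisson_distance <- function(a, b, cap = 10) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  if (length(av) != length(bv)) stop("aligned rows differ in length")
  ok <- av != "-" & bv != "-"
  if (!any(ok)) stop("no comparable columns")
  p <- mean(av[ok] != bv[ok])
  if (p >= 1) return(structure(cap, saturated = TRUE))
  structure(-log(1 - p), saturated = FALSE)
}

#' Pairwise Poisson distance matrix of aligned rows
#'
#' @param rows named character vector of equal-length aligned sequences
#' @param cap saturation cap, see [poisson_distance()]
#' @return symmetric numeric matrix with taxon dimnames
#' @export
distance_matrix <- function(rows, cap = 10) {
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- as.numeric(poisson_distance(rows[[i]], rows[[j]],
                                                      cap = cap))
  }
  D
}

#' Saitou-Nei neighbor-joining tree from a distance matrix
#'
#' Standard Q-criterion agglomeration; negative branch lengths are clamped
#' to 0 and ties in the Q matrix are broken by the smallest (i, j) index
#' pair, so the result is deterministic.
#'
#' @param D symmetric distance matrix with taxon dimnames (>= 3 taxa)
#' @return an unrooted [ape::phylo] tree with branch lengths
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  reps <- labels  # newick fragment per active node
  active <- D
  while (nrow(active) > 3L) {
    m <- nrow(active)
    rs <- rowSums(active)
    Q <- (m - 2) * active - outer(rs, rs, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    i <- best[[1]]; j <- best[[2]]
    bi <- active[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    bj <- active[i, j] - bi
    bi <- max(0, bi); bj <- max(0, bj)
    newrep <- sprintf("(%s:%.10g,%s:%.10g)", reps[i], bi, reps[j], bj)
    dk <- (active[i, -c(i, j)] + active[j, -c(i, j)] - active[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    nxt <- rbind(cbind(active[keep, keep, drop = FALSE], dk),
                 c(dk, 0))
    reps <- c(reps[keep], newrep)
    rownames(nxt) <- colnames(nxt) <- NULL
    active <- nxt
  }
  d12 <- active[1, 2]; d13 <- active[1, 3]; d23 <- active[2, 3]
  b1 <- max(0, (d12 + d13 - d23) / 2)
  b2 <- max(0, (d12 + d23 - d13) / 2)
  b3 <- max(0, (d13 + d23 - d12) / 2)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 reps[1], b1, reps[2], b2, reps[3], b3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree of aligned sequences
#'
#' Resamples alignment columns with replacement, rebuilds the Poisson
#' distance matrix and NJ tree per replicate, and writes bipartition
#' frequencies (0-100) onto the internal nodes of the full-data tree.
#'
#' @param rows named character vector of equal-length aligned sequences
#'   (>= 4 taxa)
#' @param n_reps number of bootstrap replicates (0 = no supports)
#' @param seed integer seed for the column resampling
#' @param cap saturation cap for distances
#' @return an [ape::phylo] tree; internal-node labels hold supports when
#'   `n_reps > 0`
#' @export
bootstrap_support <- function(rows, n_reps = 2000L, seed = NULL, cap = 10) {
  stopifnot(length(rows) >= 4L)
  L <- unique(nchar(rows))
  if (length(L) != 1L) stop("rows are not aligned (unequal lengths)")
  tree <- neighbor_joining(distance_matrix(rows, cap = cap))
  if (n_reps <= 0L) return(tree)
  if (!is.null(seed)) set.seed(seed)
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  reps <- vector("list", n_reps)
  for (b in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rs <- apply(mat[, cols, drop = FALSE], 1, paste0, collapse = "")
    reps[[b]] <- neighbor_joining(distance_matrix(rs, cap = cap))
  }
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  tree$node.label <- as.character(round(100 * counts / n_reps))
  tree
}

#' Align a set of sequences to a common reference
#'
#' Pairwise-aligns every sequence to the longest member (ties broken by
#' name) and maps the alignments onto the reference columns; insertions
#' relative to the reference are dropped. Gives a quick profile suitable for
#' distance-based trees of closely related domain sequences; it is not a
#' full multiple-sequence alignment.
#'
#' @param seqs named character vector of amino-acid sequences
#' @param ... passed to [align_proteins()]
#' @return named character vector of equal-length rows, plus attribute
#'   `reference` naming the reference sequence
#' @export
align_to_reference <- function(seqs, ...) {
  stopifnot(length(seqs) >= 2L, !is.null(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  ref_name <- names(seqs)[ord[1]]
  ref <- seqs[[ref_name]]
  L <- nchar(ref)
  rows <- vapply(names(seqs), function(id) {
    if (id == ref_name) return(ref)
    al <- align_proteins(ref, seqs[[id]], ...)
    rv <- strsplit(al$a, "")[[1]]  # reference row
    qv <- strsplit(al$b, "")[[1]]
    paste0(qv[rv != "-"], collapse = "")  # drop insertions vs reference
  }, "")
  structure(rows, reference = ref_name)
}
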