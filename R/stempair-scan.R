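#' Configuration for the inverted repeat-pair scan
#'
#' @param max_inner_distance Maximum inner gap (bp) between the paired
#'   repeats; default 10,000. The exemplar exon-skipping pairs sit 1,448 and
#'   4,188 bp apart.
#' @param min_identity_fraction Minimum stem identity
#'   (`matches / shorter length`), default 0.6.
#' @param match,mismatch,gap Global-alignment scores used by
#'   [pair_identity()]; defaults +1/-1/-2.
#' @param lambda Distance-decay scale (bp) of the ranking score, default
#'   2,000. The score is `identity_fraction * exp(-inner_distance / lambda)`,
#'   a heuristic for the kinetic advantage of proximal stems: a nascent
#'   transcript can fold a short-range stem before the distal partner is
#'   even transcribed.
#' @param gapless If `TRUE`, [pair_identity()] counts matches over the best
#'   ungapped offset instead of the gapped global alignment. A stem built as
#'   an exact reverse complement with `k` substitutions has gapless identity
#'   `length - k` by construction; the gapped optimum can exceed it.
#' @return A `pair_scan_config` list.
#' @export
pair_scan_config <- function(max_inner_distance = 10000L,
                             min_identity_fraction = 0.6,
                             match = 1, mismatch = -1, gap = -2,
                             lambda = 2000, gapless = FALSE) {
  stopifnot(max_inner_distance > 0L,
            min_identity_fraction >= 0, min_identity_fraction <= 1,
            lambda > 0)
  structure(list(max_inner_distance = as.integer(max_inner_distance),
                 min_identity_fraction = min_identity_fraction,
                 match = match, mismatch = mismatch, gap = gap,
                 lambda = lambda, gapless = isTRUE(gapless)),
            class = "pair_scan_config")
}

#' Stem identity of a putative inverted repeat pair
#'
#' Globally aligns `seq_a` against the reverse complement of `seq_b`
#' (Needleman-Wunsch via `Biostrings::pairwiseAlignment`) and counts
#' identical aligned positions. The denominator is the length of the shorter
#' sequence, so a perfect stem of an L-bp repeat against its exact reverse
#' complement scores `L / L`.
#'
#' @param seq_a,seq_b Character strings or `DNAString`s over `A,C,G,T,N`.
#' @param config A [pair_scan_config()] supplying alignment scores.
#' @return Named integer vector `c(matches, denominator)`.
#' @export
pair_identity <- function(seq_a, seq_b, config = pair_scan_config()) {
  a <- toupper(as.character(seq_a)); b <- toupper(as.character(seq_b))
  if (nchar(a) == 0L || nchar(b) == 0L) stop("empty sequence")
  brc <- revcomp_chr(b)
  if (config$gapless) {
    ca <- strsplit(a, "", fixed = TRUE)[[1]]
    cb <- strsplit(brc, "", fixed = TRUE)[[1]]
    if (length(ca) > length(cb)) { tmp <- ca; ca <- cb; cb <- tmp }
    best <- 0L
    for (off in 0:(length(cb) - length(ca)))
      best <- max(best, sum(ca == cb[seq_along(ca) + off]))
    return(c(matches = as.integer(best),
             denominator = min(nchar(a), nchar(b))))
  }
  letters <- c("A", "C", "G", "T", "N")
  mat <- matrix(config$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(mat) <- config$match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(brc),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = abs(config$gap))
  c(matches = Biostrings::nmatch(pa),
    denominator = min(nchar(a), nchar(b)))
}

#' Inner distance between two repeats
#'
#' The gap from the end of the upstream repeat to the start of the
#' downstream repeat in 0-based half-open coordinates, so abutting repeats
#' are 0 bp apart.
#'
#' @param r1,r2 [genomic_interval()]s with `r1` strictly upstream
#'   (`r1$end <= r2$start`).
#' @return Integer bp.
#' @export
inner_distance <- function(r1, r2) {
  if (r1$chrom != r2$chrom) stop("repeats on different chromosomes")
  if (r2$start < r1$end)
    stop("repeats overlap or are out of order (need r1 strictly upstream)")
  r2$start - r1$end
}

#' Reading-frame consequence of skipping trapped exons
#'
#' Skipping is in frame iff the summed CDS length of the trapped exons is
#' divisible by 3; otherwise the downstream reading frame shifts. Trapped
#' exons carrying no CDS (pure UTR) are in frame by construction and the
#' result is flagged.
#'
#' @param trapped Integer vector of exon ordinals (transcript 5'->3' order).
#' @param tx A [transcript_model()].
#' @return List with `effect` (`"in_frame"` or `"frameshift"`),
#'   `trapped_cds_bp`, and `noncoding` flag.
#' @export
frame_effect <- function(trapped, tx) {
  stopifnot(all(trapped >= 1L), all(trapped <= nrow(tx$exons)))
  total <- 0L
  for (i in trapped) {
    e <- tx$exons[i, ]
    if (nrow(tx$cds))
      total <- total + sum(pmax(0L, pmin(e$end, tx$cds$end) -
                                  pmax(e$start, tx$cds$start)))
  }
  list(effect = if (total %% 3L == 0L) "in_frame" else "frameshift",
       trapped_cds_bp = as.integer(total),
       noncoding = total == 0L)
}

# Intron ordinal (transcript order) fully containing an interval, or NA.
host_intron <- function(iv, introns_genomic) {
  for (i in seq_len(nrow(introns_genomic)))
    if (iv$start >= introns_genomic$start[i] && iv$end <= introns_genomic$end[i])
      return(i)
  NA_integer_
}

#' Find exon-flanking inverted intronic repeat pairs
#'
#' Scans all pairs of annotated repeats lying fully inside distinct introns
#' of a transcript, keeps pairs with opposite strand annotations whose inner
#' gap does not exceed `max_inner_distance` and whose stem identity
#' ([pair_identity()] on the genomic sequences) reaches
#' `min_identity_fraction`, and reports for each the trapped exons (those
#' strictly between the two host introns, which an RNA stem formed by the
#' pair would loop out of the pre-mRNA), the reading-frame consequence of
#' skipping them, and the ranking score. Pairs may span non-adjacent
#' introns, trapping several exons.
#'
#' @param tx A [transcript_model()] with at least 3 exons.
#' @param repeats data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `family` (e.g. RepeatMasker BED6 via [read_repeats_bed()]).
#' @param genome Named `DNAStringSet`.
#' @param config A [pair_scan_config()]. The scanner defaults to gapless
#'   stem identity: the gapped global alignment of two *unrelated* repeats of
#'   unequal length routinely pushes matches/shorter-length past 0.6 (the
#'   aligner gaps its way to the best corridor), which would drown true
#'   pairs in decoys at the default identity threshold; ungapped identity of
#'   unrelated sequences stays near 0.25.
#' @return A data.frame of candidates, ranked by [rank_candidates()]; zero
#'   rows when the transcript has fewer than 3 exons or no qualifying pair.
#' @export
find_inverted_pairs <- function(tx, repeats, genome,
                                config = pair_scan_config(gapless = TRUE)) {
  empty <- data.frame(up_family = character(), up_start = integer(),
                      up_end = integer(), up_strand = character(),
                      down_family = character(), down_start = integer(),
                      down_end = integer(), down_strand = character(),
                      intron_up = integer(), intron_down = integer(),
                      trapped_exons = character(), inner_distance = integer(),
                      identity_matches = integer(),
                      identity_denominator = integer(),
                      identity_fraction = numeric(), frame = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (nrow(tx$exons) < 3L) return(empty)
  introns <- tx_introns(tx)  # transcript order
  reps <- repeats[repeats$chrom == tx$chrom, , drop = FALSE]
  if (nrow(reps) < 2L) return(empty)
  reps$intron <- vapply(seq_len(nrow(reps)), function(i)
    host_intron(genomic_interval(reps$chrom[i], reps$start[i], reps$end[i],
                                 reps$strand[i]), introns), integer(1))
  reps <- reps[!is.na(reps$intron), , drop = FALSE]
  if (nrow(reps) < 2L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(reps))) for (j in seq_len(nrow(reps))) {
    if (reps$intron[i] >= reps$intron[j]) next      # transcript order i < j
    if (reps$strand[i] == reps$strand[j]) next      # inverted orientation
    # Genomic ordering for the inner gap (on "-" transcripts the upstream
    # repeat is genomically rightmost).
    gi <- genomic_interval(reps$chrom[i], reps$start[i], reps$end[i])
    gj <- genomic_interval(reps$chrom[j], reps$start[j], reps$end[j])
    left <- if (gi$start <= gj$start) gi else gj
    right <- if (gi$start <= gj$start) gj else gi
    if (right$start < left$end) next
    d <- inner_distance(left, right)
    if (d > config$max_inner_distance) next
    seq_i <- as.character(Biostrings::subseq(genome[[tx$chrom]],
                                             gi$start + 1L, gi$end))
    seq_j <- as.character(Biostrings::subseq(genome[[tx$chrom]],
                                             gj$start + 1L, gj$end))
    id <- pair_identity(seq_i, seq_j, config)
    frac <- id[["matches"]] / id[["denominator"]]
    if (frac < config$min_identity_fraction) next
    trapped <- (reps$intron[i] + 1L):reps$intron[j]
    fe <- frame_effect(trapped, tx)
    rows[[length(rows) + 1L]] <- data.frame(
      up_family = reps$family[i], up_start = reps$start[i],
      up_end = reps$end[i], up_strand = reps$strand[i],
      down_family = reps$family[j], down_start = reps$start[j],
      down_end = reps$end[j], down_strand = reps$strand[j],
      intron_up = reps$intron[i], intron_down = reps$intron[j],
      trapped_exons = paste(trapped, collapse = ","),
      inner_distance = d, identity_matches = id[["matches"]],
      identity_denominator = id[["denominator"]],
      identity_fraction = frac, frame = fe$effect,
      score = NA_real_, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  rank_candidates(do.call(rbind, rows), config)
}

#' Rank inverted-pair candidates
#'
#' Score = `identity_fraction * exp(-inner_distance / lambda)`: at equal
#' identity the proximal pair wins (the exemplar 1,448-bp pair outranks its
#' 4,188-bp competitor), at equal distance the higher-identity stem wins.
#' Ties break by smaller inner distance, then genomic position.
#'
#' @param candidates Candidate data.frame from [find_inverted_pairs()].
#' @param config A [pair_scan_config()].
#' @return The same data.frame with `score` filled, sorted best-first.
#' @export
rank_candidates <- function(candidates, config = pair_scan_config()) {
  if (nrow(candidates) == 0L) return(candidates)
  candidates$score <- candidates$identity_fraction *
    exp(-candidates$inner_distance / config$lambda)
  ord <- order(-candidates$score, candidates$inner_distance,
               candidates$up_start, candidates$down_start)
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read repeat annotations from a BED6 file
#'
#' The name field carries the repeat family (RepeatMasker convention);
#' the strand column gives the annotated orientation.
#'
#' @param path Path to a BED6 file.
#' @return data.frame with `chrom`, `start`, `end`, `family`, `strand`.
#' @export
read_repeats_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             family = if (!is.null(gr$name)) gr$name else NA_character_,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}
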