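#' Build a transcript model
#'
#' Exon/CDS structure of one transcript, with intervals 0-based half-open on
#' the genome. Exons are stored sorted 5' to 3' on the transcript strand and
#' must not overlap; CDS segments must lie within exons.
#'
#' @param gene_id,transcript_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with columns `start`, `end` (genomic).
#' @param cds data.frame with columns `start`, `end`, or `NULL` for a
#'   non-coding transcript.
#' @return A `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, chrom, strand, exons,
                             cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
  if (!is.null(cds)) {
    cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  }
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  if (nrow(exons) > 1L && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("exons overlap")
  if (is.null(cds)) cds <- data.frame(start = integer(), end = integer())
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  for (i in seq_len(nrow(cds))) {
    inside <- any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    if (!inside) stop("CDS segment outside exons")
  }
  if (strand == "-") {  # 5'->3' order on the transcript strand
    exons <- exons[rev(seq_len(nrow(exons))), , drop = FALSE]
    cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  }
  rownames(exons) <- rownames(cds) <- NULL
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%d-%d(%s), %d exons, CDS %d bp\n",
              x$transcript_id, x$gene_id, x$chrom,
              min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), sum(x$cds$end - x$cds$start)))
  invisible(x)
}

tx_span <- function(tx) c(min(tx$exons$start), max(tx$exons$end))

#' Spliced (exonic) length of a transcript in bp
#' @param tx A [transcript_model()].
#' @export
spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Introns of a transcript, in transcript order
#'
#' @param tx A [transcript_model()].
#' @return data.frame with genomic `start`, `end` per intron; row `i` is the
#'   intron between exon `i` and exon `i + 1` in transcript (5'->3') order.
#' @export
tx_introns <- function(tx) {
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  n <- nrow(ex)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  introns <- data.frame(start = ex$end[-n], end = ex$start[-1])
  if (tx$strand == "-") introns <- introns[rev(seq_len(n - 1L)), , drop = FALSE]
  rownames(introns) <- NULL
  introns
}

#' Select the representative transcript of a gene
#'
#' The screen's rule: the longest transcript with the most exons. Exon count
#' is the primary key, spliced length breaks ties, and the lexicographically
#' smallest transcript id makes the choice deterministic.
#'
#' @param transcripts Non-empty list of [transcript_model()] for one gene.
#' @return The selected [transcript_model()].
#' @export
select_transcript <- function(transcripts) {
  if (length(transcripts) == 0L) stop("no transcripts supplied")
  nex <- vapply(transcripts, function(t) nrow(t$exons), integer(1))
  len <- vapply(transcripts, spliced_length, integer(1))
  ids <- vapply(transcripts, function(t) t$transcript_id, character(1))
  ord <- order(-nex, -len, ids)
  transcripts[[ord[1]]]
}

revcomp_chr <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Genomic coordinates (0-based) of CDS positions in translation order.
cds_genomic_positions <- function(tx) {
  segs <- tx$cds
  pos <- integer(0)
  for (i in seq_len(nrow(segs))) {
    p <- segs$start[i]:(segs$end[i] - 1L)
    if (tx$strand == "-") p <- rev(p)
    pos <- c(pos, p)
  }
  pos
}

# CDS nucleotide string in translation order from a genome (DNAStringSet).
# tx$cds rows are already in transcript (5'->3') order; on the "-" strand each
# segment is reverse-complemented.
cds_sequence <- function(tx, genome) {
  chrom_seq <- genome[[tx$chrom]]
  parts <- vapply(seq_len(nrow(tx$cds)), function(i) {
    p <- as.character(Biostrings::subseq(chrom_seq, tx$cds$start[i] + 1L,
                                         tx$cds$end[i]))
    if (tx$strand == "-") revcomp_chr(p) else p
  }, character(1))
  paste(parts, collapse = "")
}

# no.init.codon: these are interior codons, so alternative initiators such as
# CTG must not be forced to Met. Single codons go through the GENETIC_CODE
# table directly; it is much cheaper than building a DNAString.
translate_chr <- function(s) {
  if (nchar(s) == 0L) return("")
  if (nchar(s) == 3L) {
    aa <- unname(Biostrings::GENETIC_CODE[s])
    return(if (is.na(aa)) "X" else aa)
  }
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

in_any <- function(p, segs) any(p >= segs$start & p < segs$end)

#' Classify the coding consequence of a variant against a transcript
#'
#' Positional classes come from exon/CDS overlap; the splice region is the
#' two intronic bases flanking each exon (the canonical donor/acceptor
#' dinucleotides) and takes precedence over coding classes. CDS SNVs are
#' translated codon-wise with the standard genetic code, strand-aware. For
#' indels the rule is the length of affected CDS modulo 3: in-frame when
#' divisible, frameshift otherwise. Because the screen's calls use the
#' ingroup genome as the reference allele, a lineage-specific *insertion* is
#' ingroup sequence whose removal is tested (in-frame -> `inframe_insertion`)
#' and a lineage-specific *deletion* is an outgroup segment whose presence is
#' tested at a width-0 anchor (in-frame -> `inframe_deletion`).
#'
#' @param variant One row of a variant table (list or 1-row data.frame with
#'   `kind`, `chrom`, `start`, `end`, `ingroup_allele`, `outgroup_alleles`).
#' @param tx A [transcript_model()].
#' @param genome A named [Biostrings::DNAStringSet] (names = chromosomes).
#' @param alt For SNVs, the alternative base; defaults to the first outgroup
#'   allele differing from the ingroup base.
#' @param flank_bp Width of the upstream/downstream flank classes.
#' @return A list with `class` (one of `flank_upstream`, `flank_downstream`,
#'   `intronic`, `splice_region`, `utr`, `synonymous`, `missense`,
#'   `inframe_insertion`, `inframe_deletion`, `frameshift`, `stop_gained`,
#'   `stop_lost`) and `protein_change` (list `pos`, `ref`, `alt`; only for
#'   the four single-residue classes).
#' @export
classify_consequence <- function(variant, tx, genome, alt = NULL,
                                 flank_bp = 10000L) {
  v <- as.list(variant)
  span <- tx_span(tx)
  no_change <- list(class = NA_character_, protein_change = NULL)
  # Flank classes, oriented by transcript strand; anything outside the gene
  # body lands here, however far.
  if (v$end <= span[1] || v$start >= span[2]) {
    before <- v$end <= span[1]
    upstream <- (before && tx$strand == "+") || (!before && tx$strand == "-")
    return(list(class = if (upstream) "flank_upstream" else "flank_downstream",
                protein_change = NULL))
  }
  # Splice region: the 2 intronic bases each side of every junction.
  introns <- tx_introns(tx)
  vstart <- v$start
  vend <- if (v$end > v$start) v$end else v$start + 1L  # width-0 anchors probe the gap
  for (i in seq_len(nrow(introns))) {
    s <- introns$start[i]; e <- introns$end[i]
    don <- c(s, min(s + 2L, e)); acc <- c(max(e - 2L, s), e)
    if ((vstart < don[2] && vend > don[1]) || (vstart < acc[2] && vend > acc[1]))
      return(list(class = "splice_region", protein_change = NULL))
  }
  ex <- tx$exons
  in_exon <- any(vstart < ex$end & vend > ex$start)
  cds <- tx$cds
  overlaps_cds <- nrow(cds) > 0L && any(vstart < cds$end & vend > cds$start)
  if (v$kind == "SNV") {
    if (!in_exon) return(list(class = "intronic", protein_change = NULL))
    if (!overlaps_cds) return(list(class = "utr", protein_change = NULL))
    gpos <- cds_genomic_positions(tx)
    cpos <- match(v$start, gpos)   # 0-based position in the CDS
    ref_base <- substring(as.character(genome[[tx$chrom]]), v$start + 1L,
                          v$start + 1L)
    if (is.null(alt)) alt <- first_differing_outgroup(v, ref_base)
    if (is.null(alt) || is.na(alt))
      return(list(class = "synonymous",
                  protein_change = list(pos = (cpos - 1L) %/% 3L + 1L,
                                        ref = NA, alt = NA)))
    if (tx$strand == "-") {
      ref_base <- revcomp_chr(ref_base)
      alt <- revcomp_chr(alt)
    }
    ci <- (cpos - 1L) %/% 3L       # 0-based codon index
    off <- (cpos - 1L) %% 3L
    cds_seq <- cds_sequence(tx, genome)
    codon <- substring(cds_seq, ci * 3L + 1L, ci * 3L + 3L)
    alt_codon <- codon
    substring(alt_codon, off + 1L, off + 1L) <- alt
    ref_aa <- translate_chr(codon)
    alt_aa <- translate_chr(alt_codon)
    cls <- if (ref_aa == alt_aa) "synonymous"
           else if (alt_aa == "*") "stop_gained"
           else if (ref_aa == "*") "stop_lost"
           else "missense"
    return(list(class = cls,
                protein_change = list(pos = ci + 1L, ref = ref_aa, alt = alt_aa)))
  }
  # Indels.
  if (v$kind == "insertion") {
    if (!overlaps_cds) {
      if (in_exon) return(list(class = "utr", protein_change = NULL))
      return(list(class = "intronic", protein_change = NULL))
    }
    affected <- sum(pmax(0L, pmin(v$end, cds$end) - pmax(v$start, cds$start)))
    cls <- if (affected %% 3L == 0L) "inframe_insertion" else "frameshift"
    return(list(class = cls, protein_change = NULL))
  }
  if (v$kind == "deletion") {
    # Width-0 anchor: the outgroup segment would sit between v$start-1 and
    # v$start. It interrupts the CDS iff the anchor falls strictly inside a
    # CDS segment (or exactly between two CDS bases of the same segment).
    inside_cds <- nrow(cds) > 0L &&
      any(v$start > cds$start & v$start < cds$end)
    if (!inside_cds) {
      if (in_exon) return(list(class = "utr", protein_change = NULL))
      return(list(class = "intronic", protein_change = NULL))
    }
    seg <- outgroup_segment_length(v)
    cls <- if (seg %% 3L == 0L) "inframe_deletion" else "frameshift"
    return(list(class = cls, protein_change = NULL))
  }
  no_change
}

first_differing_outgroup <- function(v, ref_base) {
  if (is.null(v$outgroup_alleles) || is.na(v$outgroup_alleles)) return(NULL)
  parts <- strsplit(v$outgroup_alleles, ";", fixed = TRUE)[[1]]
  al <- sub("^[^=]+=", "", parts)
  al <- al[al %in% BASES & al != ref_base]
  if (length(al) == 0L) NULL else al[1]
}

outgroup_segment_length <- function(v) {
  if (is.null(v$outgroup_alleles) || is.na(v$outgroup_alleles)) return(0L)
  parts <- strsplit(v$outgroup_alleles, ";", fixed = TRUE)[[1]]
  al <- sub("^[^=]+=", "", parts)
  al <- al[al != "."]
  if (length(al) == 0L) return(0L)
  max(nchar(al))
}

#' Filter consequence calls to damaging candidates
#'
#' Retains SNVs scored deleterious by SIFT (`sift < sift_cut`, strict) or
#' damaging by PolyPhen (`polyphen > polyphen_cut`, strict), plus every
#' protein-sequence-altering indel (in-frame insertion/deletion or
#' frameshift) regardless of scores. Missing scores never satisfy a cut.
#'
#' @param calls data.frame with columns `kind`, `class` and numeric `sift`,
#'   `polyphen` (NA allowed).
#' @param sift_cut SIFT threshold, default 0.05.
#' @param polyphen_cut PolyPhen threshold, default 0.446.
#' @return The retained subset of `calls`.
#' @export
filter_damaging <- function(calls, sift_cut = 0.05, polyphen_cut = 0.446) {
  stopifnot(all(c("kind", "class") %in% names(calls)))
  sift <- if ("sift" %in% names(calls)) calls$sift else rep(NA_real_, nrow(calls))
  poly <- if ("polyphen" %in% names(calls)) calls$polyphen else rep(NA_real_, nrow(calls))
  snv_keep <- calls$kind == "SNV" &
    ((!is.na(sift) & sift < sift_cut) | (!is.na(poly) & poly > polyphen_cut))
  indel_keep <- calls$kind %in% c("insertion", "deletion") &
    calls$class %in% c("inframe_insertion", "inframe_deletion", "frameshift")
  calls[snv_keep | indel_keep, , drop = FALSE]
}

#' Triage a damaging candidate into false-positive categories
#'
#' Encodes the screen's three manual-inspection outcomes, checked in order
#' with first match winning: `outgroup_specific` (the two outgroups disagree
#' and one matches the ingroup state — the variant is private to the other
#' outgroup); `minor_transcript` (the coding consequence arises only on a
#' transcript other than the selected representative); and
#' `shared_aa_in_tailed_species` (at least one tailed species carries the
#' ingroup residue, so the change cannot explain taillessness). Candidates
#' surviving all three remain `candidate`.
#'
#' @param ingroup_residue Residue (or allele state) shared by the ingroup.
#' @param outgroup_residues Length-2 character vector of outgroup residues,
#'   or `NULL` when untested.
#' @param tailed_residues Named character vector of residues in other tailed
#'   species, or `NULL`.
#' @param on_selected_transcript Does the consequence arise on the selected
#'   transcript?
#' @param on_other_transcript Does it arise on a non-selected transcript?
#' @return A list with `category` and `evidence`.
#' @export
triage_variant <- function(ingroup_residue, outgroup_residues = NULL,
                           tailed_residues = NULL,
                           on_selected_transcript = TRUE,
                           on_other_transcript = FALSE) {
  if (is.null(outgroup_residues) && is.null(tailed_residues) &&
      on_selected_transcript)
    return(list(category = "candidate", evidence = "untested"))
  if (!is.null(outgroup_residues) && length(outgroup_residues) >= 2L &&
      length(unique(outgroup_residues)) > 1L &&
      ingroup_residue %in% outgroup_residues)
    return(list(category = "outgroup_specific",
                evidence = sprintf("outgroups %s disagree; one matches ingroup %s",
                                   paste(outgroup_residues, collapse = "/"),
                                   ingroup_residue)))
  if (!on_selected_transcript && on_other_transcript)
    return(list(category = "minor_transcript",
                evidence = "consequence only on a non-selected transcript"))
  if (!is.null(tailed_residues) && any(tailed_residues == ingroup_residue)) {
    who <- names(tailed_residues)[tailed_residues == ingroup_residue]
    return(list(category = "shared_aa_in_tailed_species",
                evidence = paste("ingroup residue also in tailed species:",
                                 paste(who, collapse = ","))))
  }
  list(category = "candidate", evidence = "no exclusion rule fired")
}

#' Read transcript models from a GFF3 file
#'
#' Expects `gene`, `mRNA`/`transcript`, `exon` and `CDS` records linked by
#' `ID`/`Parent` attributes, as produced by [write_locus_gff3()] or standard
#' annotation pipelines (via `rtracklayer`).
#'
#' @param path Path to a GFF3 file.
#' @return A named list of [transcript_model()] keyed by transcript id.
#' @export
read_transcripts_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  txs <- df[df$type %in% c("mRNA", "transcript"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(txs))) {
    tid <- txs$ID[i]
    gene <- if (!is.null(txs$Parent[i][[1]]) && length(txs$Parent[i][[1]]))
      as.character(txs$Parent[i][[1]]) else tid
    kids <- df[vapply(df$Parent, function(p) tid %in% as.character(p), logical(1)), ,
               drop = FALSE]
    ex <- kids[kids$type == "exon", , drop = FALSE]
    cd <- kids[kids$type == "CDS", , drop = FALSE]
    out[[tid]] <- transcript_model(
      gene_id = gene, transcript_id = tid, chrom = as.character(txs$seqnames[i]),
      strand = as.character(txs$strand[i]),
      exons = data.frame(start = ex$start - 1L, end = ex$end),
      cds = if (nrow(cd)) data.frame(start = cd$start - 1L, end = cd$end) else NULL)
  }
  out
}
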