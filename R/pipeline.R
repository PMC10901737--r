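#' Run the variant screen end-to-end
#'
#' Orchestrates slice -> call -> annotate -> filter over a set of alignment
#' blocks and gene regions: lineage-specific variants are called with
#' [screen_genes()], coding consequences are classified against the selected
#' transcript of each gene when transcripts and a genome are supplied,
#' external SIFT/PolyPhen scores are joined, and the damaging filter is
#' applied. Per-stage record counts are returned so the funnel
#' (filtered <= annotated <= called) is auditable.
#'
#' @param maf Path to a MAF file, or a list of [alignment_block()].
#' @param genes data.frame of gene regions (`gene_id`, `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param partition A [species_partition()].
#' @param config A [variant_call_config()].
#' @param transcripts Optional named list of [transcript_model()] lists (or
#'   single models), keyed by `gene_id`, for consequence annotation.
#' @param genome Optional named `DNAStringSet`.
#' @param scores Optional data.frame with `chrom`, `pos` (1-based), `allele`,
#'   `sift`, `polyphen`, joined to SNV calls.
#' @param sift_cut,polyphen_cut Damaging thresholds.
#' @return A list with `variants`, `consequences`, `filtered`, `summary`,
#'   and `log` (stage record counts).
#' @export
run_screen <- function(maf, genes, partition = species_partition(),
                       config = variant_call_config(),
                       transcripts = NULL, genome = NULL, scores = NULL,
                       sift_cut = 0.05, polyphen_cut = 0.446) {
  blocks <- if (is.character(maf)) {
    if (!file.exists(maf)) stop("screen stage [input]: no such file: ", maf)
    read_maf(maf)
  } else maf
  sc <- screen_genes(blocks, genes, partition, config)
  variants <- sc$variants
  consequences <- NULL
  if (!is.null(transcripts) && !is.null(genome) && nrow(variants)) {
    cls <- character(nrow(variants))
    for (i in seq_len(nrow(variants))) {
      gid <- variants$gene_id[i]
      txs <- transcripts[[gid]]
      if (is.null(txs)) { cls[i] <- NA_character_; next }
      tx <- if (inherits(txs, "transcript_model")) txs else select_transcript(txs)
      cls[i] <- classify_consequence(variants[i, ], tx, genome)$class
    }
    consequences <- cbind(variants, class = cls, stringsAsFactors = FALSE)
    if (!is.null(scores)) {
      key <- with(consequences,
                  paste(chrom, ifelse(kind == "deletion", start, start + 1L),
                        ingroup_allele, sep = ":"))
      skey <- with(scores, paste(chrom, pos, allele, sep = ":"))
      idx <- match(key, skey)
      consequences$sift <- scores$sift[idx]
      consequences$polyphen <- scores$polyphen[idx]
    } else {
      consequences$sift <- NA_real_
      consequences$polyphen <- NA_real_
    }
  }
  filtered <- if (!is.null(consequences))
    filter_damaging(consequences, sift_cut, polyphen_cut) else NULL
  list(variants = variants, consequences = consequences, filtered = filtered,
       summary = sc$summary,
       log = list(n_called = nrow(variants),
                  n_annotated = if (is.null(consequences)) NA_integer_
                                else nrow(consequences),
                  n_filtered = if (is.null(filtered)) NA_integer_
                               else nrow(filtered)))
}

#' Scan transcripts for exon-flanking inverted repeat pairs
#'
#' Runs [find_inverted_pairs()] over every supplied transcript and returns
#' one ranked candidate table.
#'
#' @param transcripts List of [transcript_model()] (or a single model).
#' @param repeats Repeat annotation data.frame (see [read_repeats_bed()]).
#' @param genome Named `DNAStringSet`.
#' @param config A [pair_scan_config()].
#' @return Ranked candidate data.frame with a `transcript_id` column.
#' @export
run_scan <- function(transcripts, repeats, genome,
                     config = pair_scan_config()) {
  if (inherits(transcripts, "transcript_model"))
    transcripts <- list(transcripts)
  out <- list()
  for (tx in transcripts) {
    cand <- find_inverted_pairs(tx, repeats, genome, config)
    if (nrow(cand)) {
      cand <- cbind(transcript_id = tx$transcript_id, cand,
                    stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- cand
    }
  }
  if (length(out) == 0L)
    return(cbind(data.frame(transcript_id = character()),
                 find_inverted_pairs(
                   transcript_model("g", "t", "c", "+",
                                    data.frame(start = 0L, end = 1L)),
                   data.frame(chrom = character(), start = integer(),
                              end = integer(), family = character(),
                              strand = character()),
                   NULL, config)))
  res <- do.call(rbind, out)
  res <- rank_candidates(res, config)
  res
}
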