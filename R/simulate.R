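random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

other_base <- function(b) vapply(b, function(x) sample(setdiff(BASES, x), 1L),
                                 character(1), USE.NAMES = FALSE)

#' Simulate an 8-species alignment with planted lineage-specific variants
#'
#' Emulates the screen's input: an ingroup sharing an ancestral sequence,
#' two outgroups, and planted hominoid-specific SNVs, insertions and
#' deletions. Planting follows the calling rules in reverse: an SNV gives
#' the ingroup a base differing from the outgroups; an insertion gives the
#' outgroups a gap run where the ingroup carries sequence; a deletion gaps
#' the whole ingroup over columns where both outgroups carry bases.
#' Optional background divergence mutates each outgroup branch independently
#' at non-planted columns (the ingroup stays monomorphic, so planted
#' features remain the only ingroup-shared signal). Deterministic under
#' `seed`.
#'
#' @param region_length Number of alignment columns before planting (planted
#'   variants consume these columns; insertions/deletions gap one side).
#' @param planted data.frame with columns `kind` (`SNV`, `insertion`,
#'   `deletion`), `pos` (0-based column of the planting site), `length`
#'   (1 for SNVs) and optionally `pattern` (`both`, `first`, `second`:
#'   which outgroups carry the differing/absent state; deletions require
#'   `both`). Variants must not overlap.
#' @param partition A [species_partition()].
#' @param background Per-outgroup-branch substitution probability at
#'   non-planted columns, default 0.
#' @param chrom Reference chromosome name written into the block.
#' @param ref_start Reference source start coordinate of the block.
#' @param seed Integer seed; same seed, same output.
#' @return List with `block` (an [alignment_block()]) and `truth` (a
#'   data.frame of planted variants with reference 0-based half-open
#'   coordinates as the caller should report them).
#' @export
simulate_alignment <- function(region_length, planted = NULL,
                               partition = species_partition(),
                               background = 0, chrom = "chrSim",
                               ref_start = 0L, seed = 1L) {
  if (is.null(planted))
    planted <- data.frame(kind = character(), pos = integer(),
                          length = integer(), pattern = character())
  if (!"pattern" %in% names(planted) && nrow(planted))
    planted$pattern <- "both"
  if (nrow(planted)) {
    planted$length <- as.integer(planted$length)
    planted$pos <- as.integer(planted$pos)
    stopifnot(all(planted$length >= 1L),
              all(planted$pos >= 0L),
              all(planted$pos + planted$length <= region_length),
              all(planted$kind %in% c("SNV", "insertion", "deletion")),
              all(planted$length[planted$kind == "SNV"] == 1L),
              all(planted$pattern[planted$kind == "deletion"] == "both"))
    ord <- order(planted$pos)
    planted <- planted[ord, , drop = FALSE]
    if (nrow(planted) > 1L &&
        any(planted$pos[-1] < (planted$pos + planted$length)[-nrow(planted)]))
      stop("planted variants overlap")
  }
  withr::with_seed(seed, {
    anc <- strsplit(random_dna(region_length), "", fixed = TRUE)[[1]]
    species <- c(partition$ingroup, partition$outgroups)
    m <- matrix(rep(anc, each = length(species)), nrow = length(species),
                dimnames = list(species, NULL))
    og <- partition$outgroups
    planted_cols <- rep(FALSE, region_length)
    truth_rows <- list()
    for (k in seq_len(nrow(planted))) {
      p <- planted[k, ]
      cols <- p$pos + seq_len(p$length) - 1L + 1L  # 1-based columns
      planted_cols[cols] <- TRUE
      target_og <- switch(p$pattern, both = og, first = og[1], second = og[2])
      if (p$kind == "SNV") {
        ing_base <- other_base(anc[cols])
        m[partition$ingroup, cols] <- ing_base
        # under 'both' the outgroups keep the ancestral base (both differ);
        # under 'first'/'second' the non-targeted outgroup is given the
        # ingroup base, producing an ambiguous, outgroup-discordant call
        non_target <- setdiff(og, target_og)
        if (length(non_target)) m[non_target, cols] <- ing_base
        truth_rows[[k]] <- data.frame(kind = "SNV", ingroup_allele = ing_base)
      } else if (p$kind == "insertion") {
        m[target_og, cols] <- "-"
        truth_rows[[k]] <- data.frame(
          kind = "insertion",
          ingroup_allele = paste(anc[cols], collapse = ""))
      } else {
        m[partition$ingroup, cols] <- "-"
        truth_rows[[k]] <- data.frame(kind = "deletion", ingroup_allele = "")
      }
    }
    if (background > 0) {
      for (o in og) {
        hit <- which(!planted_cols & stats::runif(region_length) < background)
        if (length(hit)) m[o, hit] <- other_base(m[o, hit])
      }
    }
    rows <- data.frame(
      species = species,
      chrom = ifelse(species == partition$reference, chrom,
                     paste0(chrom, "_", species)),
      start = ifelse(species == partition$reference, as.integer(ref_start), 0L),
      size = NA_integer_, strand = "+",
      src_size = as.integer(region_length + ref_start + 1000L),
      text = apply(m, 1L, paste, collapse = ""),
      stringsAsFactors = FALSE)
    rows$size <- nchar(gsub("-", "", rows$text, fixed = TRUE))
    block <- alignment_block(rows, score = 0)

    # Reference coordinates of the planted features, as the caller reports.
    pos_map <- ref_positions(block, partition$reference)
    truth <- NULL
    if (nrow(planted)) {
      truth <- do.call(rbind, truth_rows[!vapply(truth_rows, is.null, logical(1))])
      truth$chrom <- chrom
      st <- en <- integer(nrow(planted))
      for (k in seq_len(nrow(planted))) {
        cols <- planted$pos[k] + seq_len(planted$length[k])
        if (planted$kind[k] == "deletion") {
          nxt <- pos_map[-seq_len(max(cols))]
          nxt <- nxt[!is.na(nxt)]
          st[k] <- en[k] <- if (length(nxt)) nxt[1] else
            as.integer(ref_start) + sum(!is.na(pos_map))
        } else {
          st[k] <- pos_map[cols[1]]
          en[k] <- pos_map[cols[length(cols)]] + 1L
        }
      }
      truth$start <- st; truth$end <- en
      truth <- truth[order(truth$start, truth$kind),
                     c("kind", "chrom", "start", "end", "ingroup_allele")]
      rownames(truth) <- NULL
    } else {
      truth <- data.frame(kind = character(), chrom = character(),
                          start = integer(), end = integer(),
                          ingroup_allele = character())
    }
    list(block = block, truth = truth)
  })
}

#' Random non-overlapping variant layout for [simulate_alignment()]
#'
#' Draws `n_snv` + `n_ins` + `n_del` planting sites uniformly without
#' overlap (one spacer column between consecutive variants so indel runs
#' never merge across plantings).
#'
#' @param region_length Alignment length in columns.
#' @param n_snv,n_ins,n_del Counts per kind.
#' @param indel_length_range Inclusive range of indel lengths.
#' @param seed Integer seed.
#' @return A `planted` data.frame for [simulate_alignment()].
#' @export
random_planting <- function(region_length, n_snv, n_ins, n_del,
                            indel_length_range = c(1L, 8L), seed = 1L) {
  withr::with_seed(seed, {
    kinds <- sample(c(rep("SNV", n_snv), rep("insertion", n_ins),
                      rep("deletion", n_del)))
    lens <- ifelse(kinds == "SNV", 1L,
                   sample(indel_length_range[1]:indel_length_range[2],
                          length(kinds), replace = TRUE))
    need <- sum(lens) + length(lens) + 1L  # spacers
    if (need > region_length)
      stop("region too short for requested planting")
    # place sequentially with random spacing
    slack <- region_length - need
    gaps <- if (length(lens))
      diff(c(0, sort(sample(0:slack, length(lens), replace = TRUE)))) else integer()
    pos <- integer(length(lens))
    cur <- 1L
    for (i in seq_along(lens)) {
      cur <- cur + gaps[i]
      pos[i] <- cur
      cur <- cur + lens[i] + 1L
    }
    data.frame(kind = kinds, pos = pos, length = lens, pattern = "both",
               stringsAsFactors = FALSE)
  })
}

#' Simulate a multi-exon gene locus with planted inverted repeat pairs
#'
#' Emulates the exemplar locus geometry (exon ... intron ... exon with
#' opposite-orientation intronic repeats flanking internal exons). Each
#' planted pair writes a random upstream repeat into its host intron and the
#' reverse complement of that sequence -- with a requested number of
#' substitutions -- into the downstream host intron, annotated on the
#' opposite strand, so gapless stem identity is `length - substitutions`
#' out of `length` by construction.
#'
#' @param exon_sizes Integer vector of exon lengths (bp), 5'->3'.
#' @param intron_sizes Integer vector of intron lengths, length
#'   `length(exon_sizes) - 1`.
#' @param pairs data.frame with columns `intron_up`, `intron_down`
#'   (1-based intron ordinals), `length`, `substitutions`, and optionally
#'   `offset_up` (bp of the repeat start into the upstream intron, default
#'   10) and `family_up`/`family_down` labels.
#' @param cds_exons Integer vector of coding exon ordinals (default: all);
#'   their full length is CDS.
#' @param chrom Chromosome name.
#' @param pad Flanking sequence (bp) added before/after the gene.
#' @param seed Integer seed.
#' @return List with `genome` (named `DNAStringSet`), `tx`
#'   ([transcript_model()]), `repeats` (data.frame for
#'   [find_inverted_pairs()]) and `truth` (planted pair manifest with
#'   expected gapless identity and trapped exons).
#' @export
simulate_locus <- function(exon_sizes, intron_sizes, pairs = NULL,
                           cds_exons = seq_along(exon_sizes),
                           chrom = "chrSim", pad = 200L, seed = 1L) {
  stopifnot(length(intron_sizes) == length(exon_sizes) - 1L)
  if (is.null(pairs))
    pairs <- data.frame(intron_up = integer(), intron_down = integer(),
                        length = integer(), substitutions = integer())
  if (!"offset_up" %in% names(pairs) && nrow(pairs)) pairs$offset_up <- 10L
  if (!"offset_down" %in% names(pairs) && nrow(pairs)) pairs$offset_down <- 10L
  if (!"family_up" %in% names(pairs) && nrow(pairs))
    pairs$family_up <- paste0("SIMREP", seq_len(nrow(pairs)), "U")
  if (!"family_down" %in% names(pairs) && nrow(pairs))
    pairs$family_down <- paste0("SIMREP", seq_len(nrow(pairs)), "D")
  withr::with_seed(seed, {
    glen <- sum(exon_sizes) + sum(intron_sizes)
    seq_chars <- strsplit(random_dna(glen + 2L * pad), "", fixed = TRUE)[[1]]
    # exon/intron genomic coordinates (0-based half-open), '+' strand gene
    ex_start <- integer(length(exon_sizes)); ex_end <- integer(length(exon_sizes))
    cur <- pad
    introns <- data.frame(start = integer(length(intron_sizes)),
                          end = integer(length(intron_sizes)))
    for (i in seq_along(exon_sizes)) {
      ex_start[i] <- cur; ex_end[i] <- cur + exon_sizes[i]
      cur <- ex_end[i]
      if (i <= length(intron_sizes)) {
        introns$start[i] <- cur
        introns$end[i] <- cur + intron_sizes[i]
        cur <- introns$end[i]
      }
    }
    reps <- list(); truth <- list()
    for (k in seq_len(nrow(pairs))) {
      p <- pairs[k, ]
      stopifnot(p$intron_up >= 1L, p$intron_down <= nrow(introns),
                p$intron_up < p$intron_down,
                p$substitutions <= p$length)
      up_start <- introns$start[p$intron_up] + p$offset_up
      up_end <- up_start + p$length
      if (up_end + 2L > introns$end[p$intron_up])
        stop("upstream repeat exceeds its host intron")
      up_seq <- random_dna(p$length)
      down_seq_chars <- strsplit(revcomp_chr(up_seq), "", fixed = TRUE)[[1]]
      if (p$substitutions > 0L) {
        at <- sample(p$length, p$substitutions)
        down_seq_chars[at] <- other_base(down_seq_chars[at])
      }
      down_start <- introns$start[p$intron_down] + p$offset_down
      down_end <- down_start + p$length
      if (down_end + 2L > introns$end[p$intron_down])
        stop("downstream repeat exceeds its host intron")
      seq_chars[(up_start + 1L):up_end] <-
        strsplit(up_seq, "", fixed = TRUE)[[1]]
      seq_chars[(down_start + 1L):down_end] <- down_seq_chars
      reps[[k]] <- data.frame(
        chrom = chrom,
        start = c(up_start, down_start), end = c(up_end, down_end),
        family = c(p$family_up, p$family_down), strand = c("+", "-"),
        stringsAsFactors = FALSE)
      truth[[k]] <- data.frame(
        family_up = p$family_up, family_down = p$family_down,
        intron_up = p$intron_up, intron_down = p$intron_down,
        up_start = up_start, up_end = up_end,
        down_start = down_start, down_end = down_end,
        inner_distance = down_start - up_end,
        identity_matches = p$length - p$substitutions,
        identity_denominator = p$length,
        trapped_exons = paste((p$intron_up + 1L):p$intron_down, collapse = ","),
        stringsAsFactors = FALSE)
    }
    if (length(reps) > 1L) {
      all_reps <- do.call(rbind, reps)
      all_reps <- all_reps[order(all_reps$start), , drop = FALSE]
      if (any(all_reps$start[-1] < all_reps$end[-nrow(all_reps)]))
        stop("planted repeats overlap; adjust offset_up/offset_down")
    }
    genome <- Biostrings::DNAStringSet(
      stats::setNames(paste(seq_chars, collapse = ""), chrom))
    tx <- transcript_model(
      gene_id = "simGene", transcript_id = "simGene.t1", chrom = chrom,
      strand = "+",
      exons = data.frame(start = ex_start, end = ex_end),
      cds = data.frame(start = ex_start[cds_exons], end = ex_end[cds_exons]))
    list(genome = genome, tx = tx,
         repeats = if (length(reps)) do.call(rbind, reps) else
           data.frame(chrom = character(), start = integer(), end = integer(),
                      family = character(), strand = character()),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame())
  })
}

#' Write a simulated locus to FASTA / GFF3 / BED files
#'
#' @param locus Result of [simulate_locus()].
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths.
#' @export
write_locus_files <- function(locus, dir, prefix = "locus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fa"))
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  bed <- file.path(dir, paste0(prefix, ".bed"))
  Biostrings::writeXStringSet(locus$genome, fa)
  write_locus_gff3(locus$tx, gff)
  rep <- locus$repeats
  gr <- GenomicRanges::GRanges(rep$chrom,
                               IRanges::IRanges(rep$start + 1L, rep$end),
                               strand = rep$strand)
  gr$name <- rep$family
  gr$score <- 0L
  rtracklayer::export(gr, bed, format = "bed")
  c(fasta = fa, gff3 = gff, bed = bed)
}

#' Write a transcript model as GFF3
#' @param tx A [transcript_model()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_locus_gff3 <- function(tx, path) {
  span <- tx_span(tx)
  lines <- c("##gff-version 3",
             sprintf("%s\ttailless\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     tx$chrom, span[1] + 1L, span[2], tx$strand, tx$gene_id),
             sprintf("%s\ttailless\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                     tx$chrom, span[1] + 1L, span[2], tx$strand,
                     tx$transcript_id, tx$gene_id))
  ex <- tx$exons[order(tx$exons$start), , drop = FALSE]
  cd <- tx$cds[order(tx$cds$start), , drop = FALSE]
  lines <- c(lines,
             sprintf("%s\ttailless\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                     tx$chrom, ex$start + 1L, ex$end, tx$strand,
                     tx$transcript_id),
             if (nrow(cd))
               sprintf("%s\ttailless\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                       tx$chrom, cd$start + 1L, cd$end, tx$strand,
                       tx$transcript_id))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate offspring of a Mendelian cross
#'
#' Draws `n` offspring genotypes from the cross's Punnett proportions, then
#' per genotype draws affected status from its penetrance and splits
#' affected animals over the tail categories by the given mix; unaffected
#' animals are long-tailed. Deterministic under `seed`.
#'
#' @param parent1,parent2 Parental genotypes, as in [expected_offspring()].
#' @param n Number of offspring (> 0).
#' @param penetrance_by_genotype Named numeric vector in `[0,1]`; genotypes
#'   absent from it have penetrance 0.
#' @param category_mix Proportions of `no_tail`, `short_tail`, `kinked_tail`
#'   among affected animals (summing to 1).
#' @param seed Integer seed.
#' @return A [phenotype_table()] with one row per offspring genotype.
#' @export
simulate_cross <- function(parent1, parent2, n,
                           penetrance_by_genotype = NULL,
                           category_mix = c(no_tail = 1, short_tail = 0,
                                            kinked_tail = 0),
                           seed = 1L) {
  if (n <= 0L) stop("n must be positive")
  if (abs(sum(category_mix) - 1) > 1e-8)
    stop("category_mix must sum to 1")
  props <- expected_offspring(parent1, parent2)
  withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1L, n, props))
    rows <- lapply(seq_along(props), function(i) {
      g <- names(props)[i]
      tot <- counts[i]
      pen <- if (!is.null(penetrance_by_genotype) &&
                 g %in% names(penetrance_by_genotype))
        penetrance_by_genotype[[g]] else 0
      aff <- stats::rbinom(1L, tot, pen)
      cat_counts <- if (aff > 0L)
        as.vector(stats::rmultinom(1L, aff, category_mix)) else c(0L, 0L, 0L)
      data.frame(genotype = g, no_tail = cat_counts[1],
                 short_tail = cat_counts[2], kinked_tail = cat_counts[3],
                 long_tail = tot - aff, total = tot,
                 stringsAsFactors = FALSE)
    })
    phenotype_table(do.call(rbind, rows))
  })
}
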