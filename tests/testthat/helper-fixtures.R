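# Shared fixtures and independent oracles used across test files.

toy_partition <- function() {
  species_partition(ingroup = c("hg38", "gorGor5", "panTro5", "panPan2",
                                "ponAbe2", "nomLeu3"),
                    outgroups = c("macNem1", "calJac3"))
}

# Build a block directly from a named vector of row texts.
block_from_texts <- function(texts, chrom = "chrT", start = 0L) {
  sp <- names(texts)
  alignment_block(data.frame(
    species = sp,
    chrom = ifelse(sp == sp[1], chrom, paste0(chrom, "_", sp)),
    start = start, size = nchar(gsub("-", "", texts, fixed = TRUE)),
    strand = "+", src_size = 100000L, text = unname(texts),
    stringsAsFactors = FALSE))
}

# Random well-formed block: random gaps, random species subset.
random_block <- function(width = 40L, species = c(toy_partition()$ingroup,
                                                  toy_partition()$outgroups),
                         gap_prob = 0.1) {
  texts <- vapply(species, function(s) {
    repeat {
      ch <- sample(c("A", "C", "G", "T", "-"), width, replace = TRUE,
                   prob = c(rep((1 - gap_prob) / 4, 4), gap_prob))
      if (any(ch != "-")) break   # MAF rows must carry sequence
    }
    paste(ch, collapse = "")
  }, character(1))
  block_from_texts(texts, start = sample(0:1000, 1))
}

# Independent single-column oracle for the calling rules, written as a
# direct transliteration of the presence/absence criteria (no sharing with
# classify_column's vectorized code path).
oracle_column_verdict <- function(column, partition,
                                  snv_rule = "any-differs",
                                  ins_rule = "any-absent") {
  ing <- partition$ingroup
  out <- partition$outgroups
  if (!all(ing %in% names(column))) return("none")
  iv <- toupper(column[ing])
  ov <- toupper(column[out])
  if (!all(out %in% names(column)) || any(is.na(ov)) || any(ov == "N"))
    return("none")
  if (any(iv == "N")) return("none")
  if (all(iv == "-")) {
    if (all(ov %in% c("A", "C", "G", "T"))) return("del_site")
    return("none")
  }
  if (!all(iv %in% c("A", "C", "G", "T"))) return("none")
  if (length(unique(iv)) != 1L) return("none")
  b <- iv[1]
  n_gap <- sum(ov == "-")
  if ((ins_rule == "any-absent" && n_gap >= 1L) ||
      (ins_rule == "both-absent" && n_gap == length(out)))
    return("ins_site")
  if (n_gap > 0L) return("none")
  n_diff <- sum(ov != b)
  if ((snv_rule == "any-differs" && n_diff >= 1L) ||
      (snv_rule == "both-differ" && n_diff == length(out)))
    return("snv")
  "none"
}

random_column <- function(partition, p_gap = 0.15, p_n = 0.05) {
  sp <- c(partition$ingroup, partition$outgroups)
  # bias toward shared ingroup states so snv/indel verdicts actually occur
  shared <- sample(c("A", "C", "G", "T", "-"), 1)
  vals <- vapply(sp, function(s) {
    if (s %in% partition$ingroup && stats::runif(1) < 0.8) shared
    else sample(c("A", "C", "G", "T", "-", "N"), 1,
                prob = c(rep((1 - p_gap - p_n) / 4, 4), p_gap, p_n))
  }, character(1))
  names(vals) <- sp
  vals
}

# Needleman-Wunsch oracle: global alignment of a vs revcomp(b); returns the
# optimal score plus the min/max number of identical aligned positions over
# all score-optimal alignments (lexicographic DP, composable because the
# objective is additive).
oracle_global_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  x <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  rc <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  y <- rev(rc[strsplit(toupper(b), "", fixed = TRUE)[[1]]])
  n <- length(x); m <- length(y)
  S <- matrix(-Inf, n + 1, m + 1)
  Mx <- matrix(0L, n + 1, m + 1)  # max matches among optimal
  Mn <- matrix(0L, n + 1, m + 1)  # min matches among optimal
  S[1, ] <- gap * (0:m); S[, 1] <- gap * (0:n)
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    eq <- x[i - 1] == y[j - 1]
    sub <- S[i - 1, j - 1] + if (eq) match else mismatch
    del <- S[i - 1, j] + gap
    ins <- S[i, j - 1] + gap
    best <- max(sub, del, ins)
    S[i, j] <- best
    mx <- -1L; mn <- .Machine$integer.max
    if (sub == best) {
      mx <- max(mx, Mx[i - 1, j - 1] + eq)
      mn <- min(mn, Mn[i - 1, j - 1] + eq)
    }
    if (del == best) { mx <- max(mx, Mx[i - 1, j]); mn <- min(mn, Mn[i - 1, j]) }
    if (ins == best) { mx <- max(mx, Mx[i, j - 1]); mn <- min(mn, Mn[i, j - 1]) }
    Mx[i, j] <- mx; Mn[i, j] <- mn
  }
  list(score = S[n + 1, m + 1], max_matches = Mx[n + 1, m + 1],
       min_matches = Mn[n + 1, m + 1])
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

revcomp_str <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# Toy coding transcript on a small genome, used by consequence tests:
# 3 exons x 30 bp fully coding, two 20 bp introns, 10 bp pads.
toy_coding_locus <- function(strand = "+", seed = 42) {
  withr::with_seed(seed, {
    g <- random_dna_str(150)
    genome <- Biostrings::DNAStringSet(setNames(g, "chrT"))
    exons <- data.frame(start = c(10L, 60L, 110L), end = c(40L, 90L, 140L))
    tx <- transcript_model("gT", "gT.t1", "chrT", strand, exons, exons)
    list(genome = genome, tx = tx)
  })
}

# Rebuild-and-translate oracle: apply an SNV to the genome, re-extract and
# translate the whole CDS, and diff the proteins.
oracle_snv_consequence <- function(pos0, alt, tx, genome) {
  g <- as.character(genome[[tx$chrom]])
  ref <- substring(g, pos0 + 1L, pos0 + 1L)
  g2 <- g
  substring(g2, pos0 + 1L, pos0 + 1L) <- alt
  extract_cds <- function(seq) {
    segs <- tx$cds[order(tx$cds$start), , drop = FALSE]
    s <- paste(vapply(seq_len(nrow(segs)), function(i)
      substring(seq, segs$start[i] + 1L, segs$end[i]), character(1)),
      collapse = "")
    if (tx$strand == "-") s <- revcomp_str(s)
    s
  }
  p1 <- as.character(Biostrings::translate(Biostrings::DNAString(extract_cds(g)),
                                           no.init.codon = TRUE))
  p2 <- as.character(Biostrings::translate(Biostrings::DNAString(extract_cds(g2)),
                                           no.init.codon = TRUE))
  if (p1 == p2) return(list(class = "synonymous"))
  d <- which(strsplit(p1, "")[[1]] != strsplit(p2, "")[[1]])[1]
  aa1 <- substring(p1, d, d); aa2 <- substring(p2, d, d)
  cls <- if (aa2 == "*") "stop_gained" else if (aa1 == "*") "stop_lost"
         else "missense"
  list(class = cls, pos = d, ref = aa1, alt = aa2)
}

snv_row <- function(chrom, pos0, ref, alt) {
  data.frame(kind = "SNV", chrom = chrom, start = pos0, end = pos0 + 1L,
             ingroup_allele = ref,
             outgroup_alleles = paste0("macNem1=", alt, ";calJac3=", alt),
             outgroup_support = "differs,differs", ambiguous_outgroup = FALSE,
             gene_id = NA_character_, block_id = "b1", stringsAsFactors = FALSE)
}
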