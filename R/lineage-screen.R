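#' Configuration of the lineage-specific variant caller
#'
#' The defaults encode the screen's published rules: an SNV is called where
#' all ingroup species share a base that differs in *any* outgroup
#' (`snv_outgroup_rule = "any-differs"`); an insertion where the ingroup
#' carries sequence absent in at least one outgroup
#' (`ins_outgroup_rule = "any-absent"`); a deletion where sequence absent from
#' the whole ingroup is present in *both* outgroups (fixed rule). The "any"
#' readings admit a small fraction of outgroup-specific false positives,
#' which the caller marks with `ambiguous_outgroup`; the stricter "both"
#' variants are offered as alternatives.
#'
#' @param snv_outgroup_rule `"any-differs"` (default) or `"both-differ"`.
#' @param ins_outgroup_rule `"any-absent"` (default) or `"both-absent"`.
#' @param require_complete_ingroup If `TRUE` (default) a column with any
#'   ingroup species missing yields no call.
#' @param min_indel_length Minimum merged run length (bp) for an indel call.
#' @param flank_bp Flank added on both sides of each gene region before
#'   screening; default 10,000 bp.
#' @return A `variant_call_config` list.
#' @export
variant_call_config <- function(snv_outgroup_rule = c("any-differs", "both-differ"),
                                ins_outgroup_rule = c("any-absent", "both-absent"),
                                require_complete_ingroup = TRUE,
                                min_indel_length = 1L,
                                flank_bp = 10000L) {
  stopifnot(flank_bp >= 0L, min_indel_length >= 1L)
  structure(list(snv_outgroup_rule = match.arg(snv_outgroup_rule),
                 ins_outgroup_rule = match.arg(ins_outgroup_rule),
                 del_outgroup_rule = "both-present",
                 require_complete_ingroup = isTRUE(require_complete_ingroup),
                 min_indel_length = as.integer(min_indel_length),
                 flank_bp = as.integer(flank_bp)),
            class = "variant_call_config")
}

BASES <- c("A", "C", "G", "T")

# Vectorized per-column verdicts over a species x column character matrix.
# Returns a list of parallel vectors: verdict, ingroup_allele, per-outgroup
# allele matrix, per-outgroup support matrix, ambiguous flag.
classify_columns_matrix <- function(m, partition, config) {
  w <- ncol(m)
  ing <- partition$ingroup
  out <- partition$outgroups
  ing_here <- intersect(ing, rownames(m))
  out_here <- intersect(out, rownames(m))
  verdict <- rep("none", w)
  allele <- rep(NA_character_, w)
  out_allele <- matrix(NA_character_, nrow = length(out), ncol = w,
                       dimnames = list(out, NULL))
  out_support <- matrix("missing", nrow = length(out), ncol = w,
                        dimnames = list(out, NULL))
  ambiguous <- rep(FALSE, w)
  if (w == 0L) {
    return(list(verdict = verdict, ingroup_allele = allele,
                outgroup_allele = out_allele, outgroup_support = out_support,
                ambiguous = ambiguous))
  }

  ing_complete <- setequal(ing_here, ing)
  if (length(ing_here) == 0L ||
      (config$require_complete_ingroup && !ing_complete)) {
    return(list(verdict = verdict, ingroup_allele = allele,
                outgroup_allele = out_allele, outgroup_support = out_support,
                ambiguous = ambiguous))
  }
  im <- m[ing_here, , drop = FALSE]
  ing_has_n <- colSums(im == "N") > 0L
  ing_same <- colSums(im == im[rep(1L, nrow(im)), , drop = FALSE]) == nrow(im)
  ing_base <- ing_same & !ing_has_n & im[1, ] %in% BASES
  ing_gap <- colSums(im == "-") == nrow(im)

  # Outgroup status per column: base / gap / N. Species absent stay "missing".
  n_out_present <- rep(0L, w)   # non-N outgroups (base or gap)
  n_out_gap <- rep(0L, w)
  n_out_base <- rep(0L, w)
  for (o in out_here) {
    ch <- m[o, ]
    out_allele[o, ] <- ch
    is_n <- ch == "N"
    out_allele[o, is_n] <- NA_character_
    n_out_present <- n_out_present + !is_n
    n_out_gap <- n_out_gap + (ch == "-")
    n_out_base <- n_out_base + (ch %in% BASES)
  }
  all_out <- length(out)
  # Decisive outgroup data: every outgroup present in the block and non-N.
  out_complete <- length(out_here) == all_out & n_out_present == all_out

  # Deletion: whole ingroup gapped, both outgroups carry bases.
  del <- ing_gap & out_complete & n_out_base == all_out
  verdict[del] <- "del_site"
  allele[del] <- ""

  # Insertion: ingroup all bases, required number of outgroups gapped.
  need_gap <- if (config$ins_outgroup_rule == "any-absent") 1L else all_out
  ins <- ing_base & out_complete & n_out_gap >= need_gap
  verdict[ins] <- "ins_site"
  allele[ins] <- im[1, ins]

  # SNV: ingroup all share a base, no outgroup gapped, required number differ.
  cand <- ing_base & out_complete & n_out_gap == 0L & !ins
  if (any(cand)) {
    n_diff <- rep(0L, w)
    for (o in out_here) n_diff <- n_diff + (cand & out_allele[o, ] != im[1, ])
    need_diff <- if (config$snv_outgroup_rule == "any-differs") 1L else all_out
    snv <- cand & n_diff >= need_diff
    verdict[snv] <- "snv"
    allele[snv] <- im[1, snv]
  }

  # Support labels and the ambiguity flag on called columns.
  called <- verdict != "none"
  if (any(called)) {
    for (o in out_here) {
      ch <- m[o, called]
      sup <- rep("missing", length(ch))
      sup[ch == "-"] <- "absent"
      ib <- im[1, called]
      sup[ch %in% BASES & ch == ib] <- "matches"
      sup[ch %in% BASES & ch != ib] <- "differs"
      # For deletion columns the ingroup has no base; a present outgroup base
      # is what supports the call.
      isdel <- verdict[called] == "del_site"
      sup[isdel & ch %in% BASES] <- "differs"
      out_support[o, called] <- sup
    }
    sup_sub <- out_support[, called, drop = FALSE]
    ambiguous[called] <- apply(sup_sub, 2L, function(s) length(unique(s)) > 1L)
  }
  list(verdict = verdict, ingroup_allele = allele,
       outgroup_allele = out_allele, outgroup_support = out_support,
       ambiguous = ambiguous)
}

#' Classify a single alignment column
#'
#' Applies the presence/absence calling rules to one column given as a named
#' species -> character map. `N` is treated as missing data: a column with
#' `N` in any decisive species yields verdict `"none"`. A column where one
#' outgroup is gapped and the other carries a (possibly differing) base is
#' treated by the gap pattern (`ins_site` under the default any-absent rule),
#' since a gapped outgroup offers no allele to compare; the
#' `ambiguous_outgroup` flag records the disagreement.
#'
#' @param column Named character vector (names are species labels) over
#'   `A,C,G,T,N,-`.
#' @param partition A [species_partition()].
#' @param config A [variant_call_config()].
#' @return A list with `verdict` (one of `none`, `snv`, `ins_site`,
#'   `del_site`), `ingroup_allele`, `outgroup_alleles`, `outgroup_support`
#'   (per-outgroup: `differs`, `matches`, `absent`, `missing`) and
#'   `ambiguous_outgroup`.
#' @export
classify_column <- function(column, partition, config = variant_call_config()) {
  m <- matrix(toupper(column), ncol = 1L, dimnames = list(names(column), NULL))
  v <- classify_columns_matrix(m, partition, config)
  list(verdict = v$verdict[1],
       ingroup_allele = v$ingroup_allele[1],
       outgroup_alleles = stats::setNames(v$outgroup_allele[, 1],
                                          rownames(v$outgroup_allele)),
       outgroup_support = stats::setNames(v$outgroup_support[, 1],
                                          rownames(v$outgroup_support)),
       ambiguous_outgroup = v$ambiguous[1])
}

empty_variant_table <- function() {
  data.frame(kind = character(), chrom = character(), start = integer(),
             end = integer(), ingroup_allele = character(),
             outgroup_alleles = character(), outgroup_support = character(),
             ambiguous_outgroup = logical(), gene_id = character(),
             block_id = character(), stringsAsFactors = FALSE)
}

collapse_named <- function(values, names) {
  paste(paste0(names, "=", ifelse(is.na(values), ".", values)), collapse = ";")
}

#' Call lineage-specific SNVs in one alignment block
#'
#' One SNV per qualifying column with a non-gap reference position;
#' coordinates are 0-based half-open on the reference assembly's forward
#' strand.
#'
#' @param block An [alignment_block()] containing the reference species.
#' @param partition A [species_partition()].
#' @param config A [variant_call_config()].
#' @param block_id Provenance label stored with each call.
#' @return A variant data.frame (columns `kind`, `chrom`, `start`, `end`,
#'   `ingroup_allele`, `outgroup_alleles`, `outgroup_support`,
#'   `ambiguous_outgroup`, `gene_id`, `block_id`).
#' @export
call_snvs <- function(block, partition, config = variant_call_config(),
                      block_id = "b1") {
  pos <- ref_positions(block, partition$reference)
  if (block_width(block) == 0L) return(empty_variant_table())
  m <- block_char_matrix(block)
  v <- classify_columns_matrix(m, partition, config)
  idx <- which(v$verdict == "snv" & !is.na(pos))
  if (length(idx) == 0L) return(empty_variant_table())
  chrom <- block$rows$chrom[block$rows$species == partition$reference]
  data.frame(kind = "SNV", chrom = chrom, start = pos[idx], end = pos[idx] + 1L,
             ingroup_allele = v$ingroup_allele[idx],
             outgroup_alleles = vapply(idx, function(j)
               collapse_named(v$outgroup_allele[, j], rownames(v$outgroup_allele)),
               character(1)),
             outgroup_support = vapply(idx, function(j)
               paste(v$outgroup_support[, j], collapse = ","), character(1)),
             ambiguous_outgroup = v$ambiguous[idx],
             gene_id = NA_character_, block_id = block_id,
             stringsAsFactors = FALSE)
}

#' Call lineage-specific insertions and deletions in one alignment block
#'
#' Maximal runs of consecutive insertion-site columns sharing an identical
#' per-outgroup absence pattern merge into one insertion whose interval spans
#' the run's reference positions; maximal runs of deletion-site columns merge
#' into one deletion reported as a width-0 anchor between the flanking
#' reference bases, with the outgroup segment recorded. Runs shorter than
#' `min_indel_length` are dropped. A run interrupted by any other column
#' splits into separate variants.
#'
#' @inheritParams call_snvs
#' @return A variant data.frame as in [call_snvs()].
#' @export
call_indels <- function(block, partition, config = variant_call_config(),
                        block_id = "b1") {
  if (block_width(block) == 0L) return(empty_variant_table())
  pos <- ref_positions(block, partition$reference)
  m <- block_char_matrix(block)
  v <- classify_columns_matrix(m, partition, config)
  chrom <- block$rows$chrom[block$rows$species == partition$reference]
  w <- length(v$verdict)
  # Anchor coordinate for reference-gap columns: the coordinate of the next
  # non-gap reference base (start-of-block runs anchor at the row start).
  ridx <- which(block$rows$species == partition$reference)
  nxt <- rev(cummin(rev(ifelse(is.na(pos), .Machine$integer.max, pos))))
  nxt[nxt == .Machine$integer.max] <-
    block$rows$start[ridx] + block$rows$size[ridx]

  # Run key: verdict plus outgroup gap pattern (insertions split on pattern).
  gap_pat <- apply(v$outgroup_allele, 2L, function(a)
    paste(ifelse(is.na(a), "?", ifelse(a == "-", "0", "1")), collapse = ""))
  key <- ifelse(v$verdict %in% c("ins_site", "del_site"),
                paste(v$verdict, gap_pat), "x")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  res <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] == "x") next
    cols <- starts[k]:ends[k]
    if (length(cols) < config$min_indel_length) next
    kind <- if (startsWith(r$values[k], "ins_site")) "insertion" else "deletion"
    og <- rownames(v$outgroup_allele)
    seg <- vapply(og, function(o) {
      s <- v$outgroup_allele[o, cols]
      if (anyNA(s)) "." else paste(s[s != "-"], collapse = "")
    }, character(1))
    sup <- vapply(og, function(o) {
      u <- unique(v$outgroup_support[o, cols])
      if (length(u) == 1L) u else "mixed"
    }, character(1))
    if (kind == "insertion") {
      st <- pos[cols[1]]; en <- pos[cols[length(cols)]] + 1L
      allele <- paste(v$ingroup_allele[cols], collapse = "")
    } else {
      st <- en <- nxt[cols[1]]
      allele <- ""
    }
    res[[length(res) + 1L]] <- data.frame(
      kind = kind, chrom = chrom, start = st, end = en,
      ingroup_allele = allele,
      outgroup_alleles = collapse_named(seg, og),
      outgroup_support = paste(sup, collapse = ","),
      ambiguous_outgroup = any(v$ambiguous[cols]),
      gene_id = NA_character_, block_id = block_id, stringsAsFactors = FALSE)
  }
  if (length(res) == 0L) return(empty_variant_table())
  do.call(rbind, res)
}

#' Screen gene regions for lineage-specific variants
#'
#' Expands each gene interval by `config$flank_bp` on both sides, slices the
#' blocks to the expanded region, calls SNVs and indels, labels calls with
#' the gene id, and summarizes counts per class. Variants falling in
#' overlapping expanded regions are counted once globally (de-duplicated by
#' kind, position and alleles) and once per gene in the per-gene table.
#'
#' @param blocks List of [alignment_block()].
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open on the reference assembly).
#' @param partition A [species_partition()].
#' @param config A [variant_call_config()].
#' @return A list with `variants` (per-gene variant table), `summary`
#'   (list `n_snv`, `n_insertion`, `n_deletion` over de-duplicated calls and
#'   a `per_gene` count table).
#' @export
screen_genes <- function(blocks, genes, partition,
                         config = variant_call_config()) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  per_gene_rows <- list()
  for (g in seq_len(nrow(genes))) {
    iv <- genomic_interval(genes$chrom[g],
                           max(0L, genes$start[g] - config$flank_bp),
                           genes$end[g] + config$flank_bp)
    hit <- FALSE
    for (bi in seq_along(blocks)) {
      sl <- slice_block(blocks[[bi]], iv, partition$reference)
      if (block_width(sl) == 0L) next
      hit <- TRUE
      vv <- rbind(call_snvs(sl, partition, config, block_id = paste0("b", bi)),
                  call_indels(sl, partition, config, block_id = paste0("b", bi)))
      if (nrow(vv)) {
        vv$gene_id <- genes$gene_id[g]
        per_gene_rows[[length(per_gene_rows) + 1L]] <- vv
      }
    }
    if (!hit)
      warning("gene ", genes$gene_id[g], " has no overlapping alignment block")
  }
  variants <- if (length(per_gene_rows)) do.call(rbind, per_gene_rows)
              else empty_variant_table()
  variants <- variants[order(variants$chrom, variants$start, variants$kind), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  key <- with(variants, paste(kind, chrom, start, end, ingroup_allele,
                              outgroup_alleles))
  dedup <- variants[!duplicated(key), , drop = FALSE]
  per_gene <- as.data.frame(table(gene_id = variants$gene_id,
                                  kind = variants$kind),
                            stringsAsFactors = FALSE)
  summary <- list(n_snv = sum(dedup$kind == "SNV"),
                  n_insertion = sum(dedup$kind == "insertion"),
                  n_deletion = sum(dedup$kind == "deletion"),
                  per_gene = per_gene)
  list(variants = variants, summary = summary)
}

#' Write a variant table as TSV
#'
#' Columns: `CHROM`, `POS` (1-based; for deletions the position of the base
#' immediately left of the width-0 anchor), `KIND`, `INGROUP_ALLELE`,
#' `OUTGROUP_ALLELES` (per outgroup `name=allele(support)`), `FLAGS`
#' (`ambiguous_outgroup` or `.`), `GENE`. Rows are sorted by chromosome and
#' position on write. [read_variants()] inverts the encoding.
#'
#' @param variants A variant data.frame from the callers.
#' @param path Output path.
#' @return Invisibly, the written data.frame.
#' @export
write_variants <- function(variants, path) {
  v <- variants[order(variants$chrom, variants$start), , drop = FALSE]
  pos1 <- ifelse(v$kind == "deletion", v$start, v$start + 1L)
  og <- mapply(function(alleles, support) {
    a <- strsplit(alleles, ";", fixed = TRUE)[[1]]
    s <- strsplit(support, ",", fixed = TRUE)[[1]]
    paste(paste0(a, "(", s, ")"), collapse = ";")
  }, v$outgroup_alleles, v$outgroup_support)
  out <- data.frame(CHROM = v$chrom, POS = pos1, KIND = v$kind,
                    INGROUP_ALLELE = ifelse(v$ingroup_allele == "", ".",
                                            v$ingroup_allele),
                    OUTGROUP_ALLELES = if (nrow(v)) og else character(),
                    FLAGS = ifelse(v$ambiguous_outgroup, "ambiguous_outgroup", "."),
                    GENE = ifelse(is.na(v$gene_id), ".", v$gene_id),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read a variant TSV written by [write_variants()]
#'
#' @param path Path to the TSV.
#' @return A variant data.frame with the caller's column layout
#'   (`block_id` is not round-tripped and is set to `NA`).
#' @export
read_variants <- function(path) {
  tt <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (nrow(tt) == 0L) return(empty_variant_table())
  pos <- as.integer(tt$POS)
  start <- ifelse(tt$KIND == "deletion", pos, pos - 1L)
  allele <- ifelse(tt$INGROUP_ALLELE == ".", "", tt$INGROUP_ALLELE)
  end <- ifelse(tt$KIND == "deletion", start, start + nchar(allele))
  parsed <- lapply(tt$OUTGROUP_ALLELES, function(s) {
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^([^=]+)=([^()]*)\\(([^)]*)\\)$", parts))
    list(alleles = paste(vapply(m, function(x) paste0(x[2], "=", x[3]),
                                character(1)), collapse = ";"),
         support = paste(vapply(m, function(x) x[4], character(1)),
                         collapse = ","))
  })
  data.frame(kind = tt$KIND, chrom = tt$CHROM, start = as.integer(start),
             end = as.integer(end), ingroup_allele = allele,
             outgroup_alleles = vapply(parsed, `[[`, character(1), "alleles"),
             outgroup_support = vapply(parsed, `[[`, character(1), "support"),
             ambiguous_outgroup = tt$FLAGS == "ambiguous_outgroup",
             gene_id = ifelse(tt$GENE == ".", NA_character_, tt$GENE),
             block_id = NA_character_, stringsAsFactors = FALSE)
}
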